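#' Scaled-down validation study design
#'
#' The package's reference ground-truth study for end-to-end pipeline
#' validation: 8 channels at the 100 Hz analysis rate, 6 subjects, with two
#' source channels (F3 and C2) sending strength-0.6 couplings to three
#' targets each (delays 2-4 samples) in the odorized settings EM, AM and AF.
#' The EF setting is an exact re-labeling of its neutral partner NF (an odor
#' manipulation with no effect at all), so its neutral contrast is
#' identically zero and the setting is dropped by the selection stage --
#' the degenerate analogue of a setting with no surviving channels. The
#' correct pipeline outcome is therefore: selections for EM/AM/AF contain
#' exactly \{F3, C2\}, EF is dropped, and the common-channel intersection is
#' \{F3, C2\}.
#'
#' @param seed master seed for the design.
#' @param duration_samples samples per recording at 100 Hz (default 800).
#' @param n_subjects subjects (default 6).
#' @return a [synth_design].
#' @export
scaled_study_design <- function(seed = 1L, duration_samples = 800L,
                                n_subjects = 6L) {
  chans <- c("F3", "F2", "C2", "P5", "P6", "PO3", "O1", "Cz")
  odor <- c("EM", "AM", "AF")
  cps <- list(
    coupling_spec("F3", "P5", 2, 0.6, odor),
    coupling_spec("F3", "P6", 3, 0.6, odor),
    coupling_spec("F3", "PO3", 4, 0.6, odor),
    coupling_spec("C2", "F2", 2, 0.6, odor),
    coupling_spec("C2", "O1", 3, 0.6, odor),
    coupling_spec("C2", "Cz", 4, 0.6, odor)
  )
  synth_design(n_channels = 8, channel_labels = chans, rate = 100,
               duration_samples = duration_samples, ar_coeff = 0.5,
               noise_sd = 1, couplings = cps, n_subjects = n_subjects,
               seed = seed, condition_alias = c(EF = "NF"))
}

#' Coupling-free null study design
#'
#' The validation design stripped of every coupling: all channels are
#' independent AR(1) noise in every condition, so any channel selected and
#' any non-empty common-channel set is a false positive.
#'
#' @inheritParams scaled_study_design
#' @return a [synth_design].
#' @export
null_study_design <- function(seed = 1L, duration_samples = 800L,
                              n_subjects = 6L) {
  chans <- c("F3", "F2", "C2", "P5", "P6", "PO3", "O1", "Cz")
  synth_design(n_channels = 8, channel_labels = chans, rate = 100,
               duration_samples = duration_samples, ar_coeff = 0.5,
               noise_sd = 1, couplings = list(), n_subjects = n_subjects,
               seed = seed)
}
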