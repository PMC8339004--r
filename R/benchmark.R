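#' Benchmark reader-study results
#'
#' Detection counts and wAFROC figures of merit from a published benchmark
#' nodule-detection reader study on a 201-image synthetic-radiograph set
#' (370 inserted lesions): nine radiologists plus two CNN detectors. Counts
#' are at the operating point used for reporting (detector confidences
#' thresholded strictly above 0.5; reader marks all counted). Shipped with
#' the package so study design and evaluation output can be sanity-checked
#' against realistic human and CNN operating points.
#'
#' @param type filter by observer type: `"all"`, `"reader"` or `"cnn"`.
#' @return tibble with columns `observer`, `type`, `tp`, `fp`, `fn`,
#'   `fom` (wAFROC figure of merit), its 95% CI bounds and standard error,
#'   and `wllf_at_02` (wLLF at the FPF = 0.2 operating point).
#' @export
reader_study_benchmark <- function(type = c("all", "reader", "cnn")) {
  type <- match.arg(type)
  path <- system.file("extdata", "reader_benchmark.csv", package = "cxrsim",
                      mustWork = TRUE)
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (type != "all") df <- df[df$type == type, ]
  df
}
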