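#' Published reference coefficients of the serum-protein modules
#'
#' The published multivariable Cox coefficient tables of the
#' gastric-cancer serum prognosis and adjuvant-therapy-selection modules
#' (MD and ND panels) that this pipeline re-implements. The prognosis
#' tables print coefficient, standard error, Wald p and hazard ratio (2
#' decimal places); the AT tables print no hazard-ratio column. Used as
#' arithmetic verification anchors, e.g. that `exp(coef)` reproduces every
#' printed hazard ratio.
#'
#' @param module `"prognosis"` or `"at_selection"`.
#' @return data.frame `panel`, `id`, `coef`, `se`, `p` (printed strings
#'   like `"<0.001"` kept verbatim) and, for prognosis, `hr`.
#' @export
reference_module_table <- function(module = c("prognosis", "at_selection")) {
  module <- match.arg(module)
  if (module == "prognosis") {
    md <- data.frame(
      panel = "MD",
      id = c("Stage", "CATC", "CATD", "CD166", "FA10", "FA11", "IBP7",
             "NCAM1", "PLSL", "ROBO4", "TRML1"),
      coef = c(0.207, -0.299, 0.512, -0.324, -0.181, 0.244, -0.072,
               -0.126, 0.172, 0.213, -0.106),
      se = c(0.051, 0.127, 0.116, 0.119, 0.143, 0.101, 0.083,
             0.102, 0.108, 0.100, 0.059),
      p = c("<0.001", "0.019", "<0.001", "0.007", "0.205", "0.015",
            "0.383", "0.215", "0.110", "0.033", "0.074"),
      hr = c(1.23, 0.74, 1.67, 0.72, 0.83, 1.28, 0.93, 0.88, 1.19,
             1.24, 0.90),
      stringsAsFactors = FALSE)
    nd <- data.frame(
      panel = "ND",
      id = c("Stage", "C1QA", "CO5", "CO7", "CO9", "FBLN1", "THRB"),
      coef = c(0.194, -0.211, 0.306, 0.313, 0.152, -0.352, -0.214),
      se = c(0.051, 0.107, 0.135, 0.138, 0.082, 0.132, 0.136),
      p = c("<0.001", "0.051", "0.025", "0.025", "0.068", "0.009",
            "0.119"),
      hr = c(1.21, 0.81, 1.36, 1.37, 1.16, 0.70, 0.81),
      stringsAsFactors = FALSE)
    rbind(md, nd)
  } else {
    md <- data.frame(
      panel = "MD",
      id = c("CA2", "CADM1", "CD166", "CO6A1", "CYTC", "DPP4", "IL1R2",
             "LAMP1", "LDHB", "MYG", "PLSL", "ROBO4", "THIO", "TRML1"),
      coef = c(-0.207, 0.408, -0.476, -0.098, 0.443, 0.138, 0.234,
               -0.124, 0.127, -0.191, -0.296, -0.309, 0.166, 0.200),
      se = c(0.092, 0.166, 0.176, 0.105, 0.168, 0.070, 0.146,
             0.109, 0.136, 0.099, 0.177, 0.118, 0.122, 0.079),
      p = c("0.026", "0.014", "0.007", "0.353", "0.009", "0.050",
            "0.110", "0.259", "0.350", "0.056", "0.096", "0.009",
            "0.173", "0.013"),
      stringsAsFactors = FALSE)
    nd <- data.frame(
      panel = "ND",
      id = c("C1QA", "C1QB", "C1QC", "FINC", "THRB", "VTDB"),
      coef = c(0.167, 0.219, -0.219, -0.256, 0.293, -0.267),
      se = c(0.120, 0.150, 0.115, 0.135, 0.161, 0.158),
      p = c("0.165", "0.145", "0.058", "0.060", "0.071", "0.093"),
      stringsAsFactors = FALSE)
    rbind(md, nd)
  }
}
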