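#' Allele configuration of a locus
#'
#' Describes a sample's copies of the assayed amplicon by methylation state.
#' The latent methylation fraction is the quantity the digestion-qPCR
#' pipeline estimates: a biparental diploid locus (one methylated maternal
#' copy, one unmethylated paternal copy) has fraction 0.5; a
#' paternal-deletion genotype carrying only the methylated maternal copy has
#' fraction 1; a fully demethylated single copy has fraction 0.
#'
#' @param methylated Non-negative integer count of methylated copies.
#' @param unmethylated Non-negative integer count of unmethylated copies.
#' @return An object of class `allele_config`.
#' @examples
#' allele_config(methylated = 1, unmethylated = 1)  # biparental diploid
#' methylation_fraction(allele_config(1, 0))        # 1: deletion genotype
#' @export
allele_config <- function(methylated = 0, unmethylated = 0) {
  stopifnot(
    length(methylated) == 1, length(unmethylated) == 1,
    is.numeric(methylated), is.numeric(unmethylated),
    methylated >= 0, unmethylated >= 0,
    methylated == round(methylated), unmethylated == round(unmethylated)
  )
  total <- methylated + unmethylated
  if (total < 1) {
    stop("allele_config requires at least one copy in total", call. = FALSE)
  }
  structure(
    list(methylated = as.integer(methylated),
         unmethylated = as.integer(unmethylated)),
    class = "allele_config"
  )
}

#' @param config An `allele_config`.
#' @return `methylation_fraction()`: methylated copies / total copies, in
#'   \[0, 1\].
#' @rdname allele_config
#' @export
methylation_fraction <- function(config) {
  stopifnot(inherits(config, "allele_config"))
  config$methylated / (config$methylated + config$unmethylated)
}

#' @export
print.allele_config <- function(x, ...) {
  cat(sprintf("<allele_config> %d methylated + %d unmethylated (m = %.3f)\n",
              x$methylated, x$unmethylated, methylation_fraction(x)))
  invisible(x)
}
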