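# Tajima's D from a haplotype matrix, with the standard variance constants
# (Tajima 1989).

#' Tajima's D
#'
#' D = (theta_pi - theta_W) / sqrt(Var-hat), where theta_pi is the mean number
#' of pairwise differences and theta_W = S / a1 is Watterson's estimator, with
#' the usual a1, a2, b1, b2, c1, c2, e1, e2 constants. Negative D indicates an
#' excess of rare variants; D >= 2 is the conventional flag for balancing
#' selection or population contraction.
#'
#' @param haplotypes matrix of 0/1 alleles, one row per haplotype, one column
#'   per site (monomorphic columns are ignored).
#' @return Tajima's D, or NA (with a warning) when there is no segregating
#'   site.
#' @export
tajimas_d <- function(haplotypes) {
  if (!is.matrix(haplotypes)) haplotypes <- as.matrix(haplotypes)
  n <- nrow(haplotypes)
  if (n < 4) stop("need at least 4 haplotypes")
  if (!all(haplotypes %in% c(0, 1))) stop("haplotypes must be 0/1")
  cnt <- colSums(haplotypes)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  if (S == 0) {
    warning("no segregating site; Tajima's D undefined")
    return(NA_real_)
  }
  p <- cnt[seg] / n
  theta_pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  num <- theta_pi - theta_w
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den == 0) return(0)
  num / den
}
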