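#' Normalized mutual information between two clusterings
#'
#' `NMI(C1, C2) = 2 I(C1, C2) / (H(C1) + H(C2))`, where `I` is the mutual
#' information of the two label assignments and `H` the entropy of each.
#' NMI is 1 for identical partitions (invariant to label renaming), and by
#' convention 1 when both entropies are zero (two single-class partitions,
#' which are necessarily identical). Items must be labelled in both
#' clusterings; pairs with an `NA` label on either side are dropped before
#' the computation, and an error is raised when no common items remain.
#'
#' @param labels_a,labels_b Label vectors of equal length (any atomic type).
#' @return NMI in `[0, 1]`.
#' @export
#' @examples
#' clustering_nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
clustering_nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("clustering_nmi(): label vectors must have equal length")
  ok <- !is.na(labels_a) & !is.na(labels_b)
  if (!any(ok))
    stop("clustering_nmi(): no items labelled in both clusterings")
  a <- as.character(labels_a[ok])
  b <- as.character(labels_b[ok])
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (ha + hb == 0) return(1)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  2 * mi / (ha + hb)
}
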