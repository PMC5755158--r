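#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A over all pedigree
#' animals: a_ii = 1 + a(sire,dam)/2 and a_ij = (a(j,sire_i) + a(j,dam_i))/2
#' for j preceding i, with unknown parents contributing zero. Entries are
#' twice the kinship coefficients; the diagonal exceeds 1 for inbred
#' animals.
#'
#' @param ped pedigree data.frame (`animal`, `sire`, `dam`); sorted
#'   internally with [sort_pedigree()].
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
numerator_relationship_matrix <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                    (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  A
}
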