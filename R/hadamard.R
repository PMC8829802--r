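#' Sylvester-construction Hadamard encoding matrix
#'
#' Builds the N x (N-1) time-encoding matrix used by Hadamard time-encoded
#' pCASL: the Sylvester Hadamard matrix of order N with its all-ones column
#' dropped. Rows are encoding states (acquired volumes), columns are
#' sub-boli; +1 means the sub-bolus is labeled in that acquisition. The
#' global sign is chosen so the first acquired volume labels every
#' sub-bolus. Columns are mutually orthogonal and each sums to zero
#' (balanced encoding).
#'
#' @param n_encode N, a power of 2, >= 2.
#' @return Integer matrix of +-1, N rows, N-1 columns.
#' @export
hadamard_matrix <- function(n_encode) {
  n <- as.integer(n_encode)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("n_encode must be a power of 2, >= 2")
  H <- matrix(1L, 1L, 1L)
  while (nrow(H) < n)
    H <- rbind(cbind(H, H), cbind(H, -H))
  H[, -1L, drop = FALSE]
}

#' Define a Hadamard time-encoding scheme
#'
#' The default reproduces an N = 8 "free-lunch" protocol: a first
#' sub-bolus with the full 2000 ms labeling duration followed by six
#' 250 ms sub-boli, with a final post-labeling delay of 200 ms.
#'
#' @param n_encode N, a power of 2.
#' @param sub_bolus_durations Labeling duration per sub-bolus, ms
#'   (length N-1, earliest first). The first may differ (free lunch).
#' @param final_pld Delay between the end of the last sub-bolus and
#'   readout, ms.
#' @return A `hadamard_scheme` with the encoding matrix attached.
#' @export
hadamard_scheme <- function(n_encode = 8,
                            sub_bolus_durations = c(2000, rep(250, 6)),
                            final_pld = 200) {
  mat <- hadamard_matrix(n_encode)
  if (length(sub_bolus_durations) != n_encode - 1L)
    stop("need exactly N - 1 sub-bolus durations")
  if (any(sub_bolus_durations <= 0)) stop("sub-bolus durations must be > 0")
  if (final_pld < 0) stop("final_pld must be >= 0")
  structure(list(n_encode = as.integer(n_encode),
                 sub_bolus_durations = as.numeric(sub_bolus_durations),
                 final_pld = as.numeric(final_pld),
                 encoding_matrix = mat),
            class = "hadamard_scheme")
}

#' Effective timing of each sub-bolus
#'
#' The effective post-labeling delay of sub-bolus k (1-indexed from the
#' earliest) is the final PLD plus the summed durations of all later
#' sub-boli; its labeling duration is its own block length. For the default
#' N = 8 free-lunch scheme this gives PLDs 1700, 1450, 1200, 950, 700,
#' 450, 200 ms with LDs 2000, 250, ..., 250 ms.
#'
#' @param scheme A [hadamard_scheme()].
#' @return List with `effective_plds` and `sub_bolus_lds`, ms, earliest
#'   sub-bolus first.
#' @export
hadamard_timing <- function(scheme) {
  stopifnot(inherits(scheme, "hadamard_scheme"))
  d <- scheme$sub_bolus_durations
  k <- length(d)
  plds <- scheme$final_pld + rev(cumsum(rev(c(d[-1], 0))))
  list(effective_plds = plds, sub_bolus_lds = d)
}
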