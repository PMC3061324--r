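# Inversion of the head system and construction of the four lead fields.

#' Invert the (deflated) head matrix
#'
#' Computes an explicit symmetric inverse (mirroring the workflow where the
#' inverse is assembled once and reused across EEG/MEG/EIT/IP gains), via a
#' symmetric indefinite solve. A direct per-right-hand-side solve path is kept
#' for cross-checking (`solve_head`).
#'
#' @param hm a deflated `bem_head_matrix`.
#' @param cond_threshold reciprocal-condition threshold below which the matrix
#'   is declared numerically singular (default 1e-12).
#' @return object of class `bem_head_inverse` with `matrix` (the dense
#'   inverse), `map`, `rcond`.
#' @export
invert_head_matrix <- function(hm, cond_threshold = 1e-12) {
  if (is.null(hm$deflation))
    stop("head matrix must be deflated before inversion (constant null space)")
  H <- hm$matrix
  rc <- rcond(H)
  if (!is.finite(rc) || rc < cond_threshold)
    stop(sprintf(paste0("head matrix numerically singular (rcond = %.3g); ",
                        "likely cause: missing deflation or a degenerate mesh"),
                 rc))
  Hi <- solve(H)
  Hi <- (Hi + t(Hi)) / 2
  structure(list(matrix = Hi, map = hm$map, rcond = rc),
            class = "bem_head_inverse")
}

#' Solve the head system for a set of right-hand sides
#'
#' Direct linear solve (no explicit inverse); used as a cross-check of
#' `invert_head_matrix`.
#'
#' @param hm a deflated `bem_head_matrix`.
#' @param B right-hand-side matrix (system dim x k).
#' @return matrix of boundary solutions X.
#' @export
solve_head <- function(hm, B) {
  solve(hm$matrix, B)
}

gain_matrix <- function(M, modality) {
  attr(M, "modality") <- modality
  class(M) <- c("bem_gain", class(M))
  M
}

re_reference <- function(M) sweep(M, 2, colMeans(M))

#' EEG lead field
#'
#' L_EEG = Head2EEG . H^-1 . SourceMatrix, re-referenced to zero mean over the
#' electrodes (average reference) unless `reference = "none"`.
#'
#' @param hinv a `bem_head_inverse`.
#' @param source_matrix system dim x n_sources right-hand sides.
#' @param h2eeg electrode transfer matrix from [head2eeg()].
#' @param reference "average" (default) or "none".
#' @return electrodes x sources gain matrix (volts per unit source).
#' @export
gain_eeg <- function(hinv, source_matrix, h2eeg, reference = "average") {
  if (ncol(h2eeg) != nrow(hinv$matrix) ||
      nrow(source_matrix) != nrow(hinv$matrix))
    stop(sprintf("shape mismatch: Head2EEG is %d x %d, H^-1 is %d x %d, source is %d x %d",
                 nrow(h2eeg), ncol(h2eeg), nrow(hinv$matrix), ncol(hinv$matrix),
                 nrow(source_matrix), ncol(source_matrix)))
  X <- hinv$matrix %*% source_matrix
  L <- h2eeg %*% X
  if (reference == "average") L <- re_reference(L)
  gain_matrix(L, "EEG")
}

#' MEG lead field
#'
#' L_MEG = Head2MEG . H^-1 . SourceMatrix + Source2MEG: the Ohmic
#' (volume-current) and primary contributions. Both parts are retrievable
#' separately from the attributes `ohmic` and `primary` for diagnostics (the
#' radial-silence property of spherical models is checked on them).
#'
#' @param hinv a `bem_head_inverse`.
#' @param source_matrix system dim x n_sources right-hand sides.
#' @param h2meg Ohmic transfer matrix from [head2meg()].
#' @param s2meg primary source matrix from [dipsource2meg()] or
#'   [surfsource2meg()].
#' @return channels x sources gain matrix (tesla) with attributes `ohmic`,
#'   `primary`.
#' @export
gain_meg <- function(hinv, source_matrix, h2meg, s2meg) {
  if (ncol(h2meg) != nrow(hinv$matrix))
    stop("shape mismatch between Head2MEG and the head inverse")
  if (!identical(dim(s2meg), c(nrow(h2meg), ncol(source_matrix))))
    stop(sprintf("Source2MEG must be %d x %d, got %d x %d",
                 nrow(h2meg), ncol(source_matrix), nrow(s2meg), ncol(s2meg)))
  ohmic <- h2meg %*% (hinv$matrix %*% source_matrix)
  L <- gain_matrix(ohmic + s2meg, "MEG")
  attr(L, "ohmic") <- ohmic
  attr(L, "primary") <- s2meg
  L
}

#' EIT lead field
#'
#' Scalp potentials of injected-current patterns:
#' L_EIT = Head2EEG . H^-1 . EITSourceMatrix (average-referenced).
#'
#' @inheritParams gain_eeg
#' @param eit_source_matrix from [assemble_eit_source_matrix()].
#' @return electrodes x patterns gain matrix (volts per ampere pattern).
#' @export
gain_eit <- function(hinv, eit_source_matrix, h2eeg, reference = "average") {
  L <- gain_eeg(hinv, eit_source_matrix, h2eeg, reference = reference)
  attr(L, "modality") <- "EIT"
  L
}

#' Internal-potential lead field
#'
#' L_IP = Head2IP . H^-1 . SourceMatrix + Source2IP. No re-referencing is
#' applied by default: internal potentials share the gauge of the boundary
#' solution; comparisons against analytic series should re-reference both
#' fields over the same evaluation set.
#'
#' @param hinv a `bem_head_inverse`.
#' @param source_matrix system dim x n_sources right-hand sides.
#' @param h2ip transfer matrix from [head2ip()].
#' @param s2ip source matrix from [dipsource2ip()].
#' @param reference "none" (default) or "average".
#' @return points x sources gain matrix (volts).
#' @export
gain_ip <- function(hinv, source_matrix, h2ip, s2ip, reference = "none") {
  if (ncol(h2ip) != nrow(hinv$matrix))
    stop("shape mismatch between Head2IP and the head inverse")
  L <- h2ip %*% (hinv$matrix %*% source_matrix) + s2ip
  if (reference == "average") L <- re_reference(L)
  gain_matrix(L, "IP")
}
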