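#' State of one self-repressing gene and its molecular species
#'
#' A single chromosomal gene copy carries two operators; the gene state
#' label records which are free: `A11` both free (fully active), `A10`/`A01`
#' one dimer bound, `A00` both bound (fully repressed). Each bound dimer
#' accounts for two DNA-bound TetR monomers, so the label implies
#' `2 * (number of 0 indices)` bound monomers. Because Venus is fused to
#' TetR, every TetR pool fluoresces: the observable total is
#' `n_tetr + n_ta + bound monomers`.
#'
#' @param gene gene state label, one of `"A11"`, `"A10"`, `"A01"`, `"A00"`.
#' @param n_tetr free TetR monomer count.
#' @param n_ta TetR-aTc complex count.
#' @param n_i internal (intracellular) free aTc count.
#' @param t time in minutes.
#' @return An object of class `system_state`.
#' @examples
#' s <- system_state("A10", n_tetr = 5)
#' bound_monomers(s)  # 2
#' total_venus(s)     # 7
#' @export
system_state <- function(gene = "A11", n_tetr = 0, n_ta = 0, n_i = 0,
                         t = 0) {
  gene <- match.arg(gene, gene_state_labels())
  counts <- c(n_tetr, n_ta, n_i)
  if (any(counts < 0) || any(counts != floor(counts)) ||
      any(!is.finite(counts)))
    stop("molecule counts must be non-negative integers", call. = FALSE)
  structure(list(gene = gene, n_tetr = n_tetr, n_ta = n_ta, n_i = n_i,
                 t = t),
            class = "system_state")
}

#' @rdname system_state
#' @export
gene_state_labels <- function() c("A11", "A10", "A01", "A00")

# 0-based index used by the C++ kernels
gene_index <- function(label) match(label, gene_state_labels()) - 1L

#' @rdname system_state
#' @param state a `system_state` object.
#' @export
bound_monomers <- function(state) {
  # two monomers per occupied operator
  c(A11 = 0L, A10 = 2L, A01 = 2L, A00 = 4L)[[state$gene]]
}

#' @rdname system_state
#' @export
total_venus <- function(state) {
  state$n_tetr + state$n_ta + bound_monomers(state)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: gene %s, TetR %d, Ta %d, I_aTc %d, t = %g min\n",
              x$gene, x$n_tetr, x$n_ta, x$n_i, x$t))
  invisible(x)
}
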