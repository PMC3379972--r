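# The DEC range state space, anagenetic rate matrix and cladogenesis table.

#' Build the DEC range state space
#'
#' Enumerates every nonempty subset of the area codebook with at most
#' `max_range_size` areas, plus the null range (a bookkeeping absorbing
#' state for lineage-wide extinction), plus any observed tip range larger
#' than `max_range_size` (the size cap constrains ranges at *nodes*; data
#' must stay representable). States are ordered canonically by size, then
#' by bit value.
#'
#' @param areas Area codebook ([default_areas()] or any ordered code vector).
#' @param max_range_size Maximum number of areas in an ancestral range
#'   (default 3).
#' @param observed Optional character vector of observed range labels; any
#'   of these larger than `max_range_size` are appended to the space.
#' @return An object of class `dec_space`: a list with `areas` (codes),
#'   `max_range_size`, `bits` (integer state bitmasks, null state first),
#'   `labels`, and `size` (areas per state).
#' @examples
#' sp <- dec_state_space(c("A", "B"), max_range_size = 2)
#' sp$labels # "0" "A" "B" "AB"
#' @export
dec_state_space <- function(areas = default_areas(), max_range_size = 3,
                            observed = NULL) {
  codes <- area_codes(areas)
  n <- length(codes)
  stopifnot(max_range_size >= 1, max_range_size <= n)
  all_bits <- seq_len(2^n - 1)
  keep <- bit_count(all_bits) <= max_range_size
  bits <- c(0L, as.integer(all_bits[keep]))
  if (!is.null(observed)) {
    ob <- unique(range_bits(observed, codes))
    if (any(ob >= 2^n)) stop("observed range outside the area codebook")
    extra <- setdiff(ob, bits)
    bits <- c(bits, extra)
  }
  sz <- bit_count(bits)
  ord <- order(sz, bits)
  bits <- bits[ord]
  structure(list(areas = codes, max_range_size = max_range_size,
                 bits = bits, labels = range_label(bits, codes),
                 size = bit_count(bits)),
            class = "dec_space")
}

#' @exportS3Method base::print
print.dec_space <- function(x, ...) {
  cat("DEC range state space: ", length(x$bits), " states (incl. null), ",
      length(x$areas), " areas, max range size ", x$max_range_size, "\n",
      sep = "")
  invisible(x)
}

state_index <- function(space, bits) match(as.integer(bits), space$bits)

#' DEC anagenetic rate matrix
#'
#' Builds the instantaneous rate matrix over the range state space: a range
#' `R` gains area `j` (if the enlarged range is in the space) at rate
#' `d * |R|` and loses any of its areas at rate `e`; losing the last area
#' absorbs the lineage in the null range. Rows sum to zero; the null row is
#' zero.
#'
#' @param space A `dec_space`.
#' @param d Dispersal rate per occupied area per Myr (>= 0).
#' @param e Local extinction rate per area per Myr (>= 0).
#' @return A square matrix with state labels as dimnames.
#' @export
dec_q_matrix <- function(space, d, e) {
  stopifnot(is.finite(d), is.finite(e), d >= 0, e >= 0)
  S <- length(space$bits)
  n <- length(space$areas)
  Q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  for (i in seq_len(S)) {
    b <- space$bits[i]
    if (b == 0L) next
    occ <- bits_areas_idx(b, n)
    for (j in seq_len(n)) {
      bitj <- bitwShiftL(1L, j - 1L)
      if (j %in% occ) {
        Q[i, state_index(space, bitwAnd(b, bitwNot(bitj)))] <- e
      } else {
        k <- state_index(space, bitwOr(b, bitj))
        if (!is.na(k)) Q[i, k] <- d * length(occ)
      }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities along a branch
#'
#' Matrix exponential `expm(Q * t)` of the anagenetic rate matrix over a
#' branch of `duration` Myr.
#'
#' @param q Rate matrix from [dec_q_matrix()].
#' @param duration Branch duration in Myr (>= 0).
#' @return A stochastic matrix (rows sum to 1).
#' @export
branch_transition_probs <- function(q, duration) {
  if (!is.numeric(duration) || length(duration) != 1 || duration < 0) {
    stop("duration must be a single nonnegative number")
  }
  P <- as.matrix(Matrix::expm(q * duration))
  P[P < 0] <- 0
  dimnames(P) <- dimnames(q)
  P
}

# Fast propagator factory: eigendecomposition of Q, validated by
# reconstruction; falls back to Matrix::expm when Q is (near-)defective.
make_propagator <- function(Q) {
  S <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      Qr <- Re(eg$vectors %*% (eg$values * Vi))
      if (max(abs(Qr - Q)) <= 1e-9 * max(1, max(abs(Q)))) {
        V <- eg$vectors; lam <- eg$values
        return(function(t) {
          P <- Re(V %*% (exp(lam * t) * Vi))
          P[P < 0] <- 0
          P
        })
      }
    }
  }
  function(t) {
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P
  }
}

#' Cladogenetic range-inheritance outcomes
#'
#' Enumerates the ordered daughter-range pairs a range can leave at a
#' speciation event under DEC. A single-area range is copied to both
#' daughters. A wider range `R` is partitioned by vicariance (`{a}` vs
#' `R \ {a}`) or by peripheral isolation (`{a}` vs the full `R`), each
#' emitted in both daughter orders; weights are uniform over the distinct
#' ordered outcomes and sum to one.
#'
#' @param range A range label (e.g. `"CD"`) or bitmask.
#' @param space A `dec_space`.
#' @return A tibble with columns `left`, `right` (range labels) and
#'   `weight`.
#' @examples
#' sp <- dec_state_space(c("A", "B"), 2)
#' cladogenetic_outcomes("AB", sp) # six ordered outcomes, weight 1/6
#' @export
cladogenetic_outcomes <- function(range, space) {
  b <- if (is.character(range)) range_bits(range, space$areas) else
    as.integer(range)
  if (b == 0L) stop("the null range has no cladogenetic outcomes")
  out <- clado_pairs(b, length(space$areas))
  keep <- !is.na(state_index(space, out$left)) &
    !is.na(state_index(space, out$right))
  out <- out[keep, , drop = FALSE]
  w <- rep(1 / nrow(out), nrow(out))
  tibble::tibble(left = range_label(out$left, space$areas),
                 right = range_label(out$right, space$areas),
                 weight = w)
}

# distinct ordered daughter pairs for a range bitmask
clado_pairs <- function(b, n_areas) {
  occ <- bits_areas_idx(b, n_areas)
  if (length(occ) == 1L) {
    return(data.frame(left = b, right = b))
  }
  L <- integer(0); R <- integer(0)
  for (j in occ) {
    aj <- bitwShiftL(1L, j - 1L)
    rem <- bitwAnd(b, bitwNot(aj))
    L <- c(L, aj, rem, aj, b)
    R <- c(R, rem, aj, b, aj)
  }
  key <- paste(L, R)
  keep <- !duplicated(key)
  data.frame(left = L[keep], right = R[keep])
}

# Precomputed cladogenesis index table over a state space: for each non-null
# parent state, the (parent, left, right, weight) quadruples, plus sparse
# accumulators used by the pruning and marginal passes.
clado_table <- function(space) {
  S <- length(space$bits)
  n <- length(space$areas)
  pidx <- integer(0); lidx <- integer(0); ridx <- integer(0); wts <- numeric(0)
  for (i in seq_len(S)) {
    b <- space$bits[i]
    if (b == 0L) next
    pr <- clado_pairs(b, n)
    li <- state_index(space, pr$left)
    ri <- state_index(space, pr$right)
    keep <- !is.na(li) & !is.na(ri)
    li <- li[keep]; ri <- ri[keep]
    k <- length(li)
    pidx <- c(pidx, rep.int(i, k))
    lidx <- c(lidx, li)
    ridx <- c(ridx, ri)
    wts <- c(wts, rep.int(1 / k, k))
  }
  K <- length(pidx)
  list(pidx = pidx, lidx = lidx, ridx = ridx, wts = wts,
       Cp = Matrix::sparseMatrix(i = pidx, j = seq_len(K), x = 1,
                                 dims = c(S, K)),
       Cl = Matrix::sparseMatrix(i = lidx, j = seq_len(K), x = 1,
                                 dims = c(S, K)),
       Cr = Matrix::sparseMatrix(i = ridx, j = seq_len(K), x = 1,
                                 dims = c(S, K)))
}
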