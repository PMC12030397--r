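# Daubechies-4 (8-tap) orthonormal scaling filter.  These are standard
# published constants of the Daubechies family.
DB4_H <- c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
           -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
           0.032883011666885197, -0.010597401785069032)

db4_g <- function() {
  L <- length(DB4_H)
  (-1)^(seq_len(L) - 1) * rev(DB4_H)
}

# one periodized analysis step: returns list(a, d), each length n/2
wpt_dec_step <- function(x) {
  n <- length(x)
  h <- DB4_H; g <- db4_g(); L <- length(h)
  k <- seq_len(n / 2) - 1L
  idx <- outer(2L * k, seq_len(L) - 1L, `+`) %% n + 1L  # (n/2) x L
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = as.numeric(xm %*% h), d = as.numeric(xm %*% g))
}

# one periodized synthesis step from (a, d) of length n/2 to length n
wpt_rec_step <- function(a, d) {
  n <- 2L * length(a)
  h <- DB4_H; g <- db4_g(); L <- length(h)
  x <- numeric(n)
  for (j in seq_len(L)) {
    pos <- (2L * (seq_along(a) - 1L) + (j - 1L)) %% n + 1L
    x[pos] <- x[pos] + h[j] * a + g[j] * d
  }
  x
}

# full 3-level wavelet packet analysis; leaves in Paley (natural) order
wpt3_leaves <- function(v) {
  nodes <- list(v)
  for (lev in 1:3) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      s <- wpt_dec_step(nodes[[i]])
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    nodes <- nxt
  }
  nodes
}

# reconstruct the full-length signal from a single Paley-order leaf
wpt3_reconstruct_leaf <- function(leaf, paley_index) {
  path <- as.integer(intToBits(paley_index))[3:1]  # bits: level1..level3 (MSB first)
  coef <- leaf
  for (lev in 3:1) {
    zero <- numeric(length(coef))
    if (path[lev] == 0L) coef <- wpt_rec_step(coef, zero)
    else coef <- wpt_rec_step(zero, coef)
  }
  coef
}

# Gray code: frequency-ordered position j (0-based) holds Paley leaf gray(j)
gray_code <- function(j) bitwXor(j, j %/% 2L)

#' Level-3 wavelet packet decomposition into 8 frequency-ordered bands
#'
#' Decomposes a 1 Hz signal with a full 3-level Daubechies-4 wavelet packet
#' tree (periodized, orthonormal), reconstructs each of the 8 leaves back to
#' signal length, and reorders the leaves from the tree's native Paley order
#' to natural frequency order, so component `k` covers
#' `[(k-1) * 0.0625, k * 0.0625]` Hz.  The 8 components sum exactly to the
#' input (perfect reconstruction).
#'
#' @param x A `uniform_signal` sampled at 1 Hz with length >= 64.  Lengths
#'   not divisible by 8 are handled by reflection padding plus cropping
#'   (reconstruction stays exact; band energies are then approximate at the
#'   edges).
#' @return A `component_set` with `method = "WPT3"`.
#' @export
wpt3 <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  if (abs(x$fs - 1) > 1e-9) stop("wpt3 expects a 1 Hz signal")
  v <- x$values
  n <- length(v)
  if (n < 64) stop("wpt3 needs at least 64 samples")
  pad <- (8 - n %% 8) %% 8
  if (pad > 0) v <- c(v, rev(v)[seq_len(pad)])
  leaves <- wpt3_leaves(v)
  comps <- vector("list", 8L)
  for (k in 1:8) {
    p <- gray_code(k - 1L)
    rec <- wpt3_reconstruct_leaf(leaves[[p + 1L]], p)
    comps[[k]] <- uniform_signal(rec[seq_len(n)], x$fs, x$t0,
                                 sprintf("WPT3 band %d", k))
  }
  centers <- (seq_len(8) - 0.5) * 0.0625
  edges <- cbind((seq_len(8) - 1) * 0.0625, seq_len(8) * 0.0625)
  component_set(comps, centers, edges, "WPT3")
}

#' Sum selected components of a decomposition
#'
#' @param cs A `component_set`.
#' @param indices 1-based indices into the frequency-ordered components.
#' @return A `uniform_signal`; attribute `band_range` records the covered
#'   frequency range in Hz.
#' @export
sum_components <- function(cs, indices) {
  stopifnot(inherits(cs, "component_set"))
  if (length(indices) == 0) stop("indices must be non-empty")
  if (any(indices < 1 | indices > length(cs$components)))
    stop("component indices out of range")
  vals <- Reduce(`+`, lapply(cs$components[indices], `[[`, "values"))
  out <- uniform_signal(vals, cs$components[[1]]$fs, cs$components[[1]]$t0,
                        sprintf("%s bands {%s}", cs$method,
                                paste(indices, collapse = ",")))
  attr(out, "band_range") <- c(min(cs$band_edges[indices, 1]),
                               max(cs$band_edges[indices, 2]))
  out
}
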