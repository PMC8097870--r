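# internal helpers shared across modules

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    abort(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", lower))
  }
  invisible(x)
}

# 8-connected (default) or 4-connected labelling of a logical matrix.
# EBImage::bwlabel is 4-connected, which splits diagonally touching
# components, so labelling is done over the pixel adjacency graph instead.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  labels <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  nr <- nrow(mask)
  pos <- match(seq_len(nr * ncol(mask)), idx)  # linear index -> vertex id
  edges <- integer(0)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (off in offsets) {
    r2 <- r + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    v2 <- pos[lin2]
    keep <- !is.na(v2)
    if (any(keep)) {
      edges <- c(edges, rbind(which(ok)[keep], v2[keep]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # deterministic labels: order components by first pixel in reading order
  # (row-major: by row, then column)
  reading <- order(r, cc)
  relabel <- integer(max(comp))
  nxt <- 0L
  for (i in reading) {
    if (relabel[comp[i]] == 0L) {
      nxt <- nxt + 1L
      relabel[comp[i]] <- nxt
    }
  }
  labels[idx] <- relabel[comp]
  labels
}

# normalised 2-D Gaussian kernel, truncated at 3 sigma (or less if the
# image is smaller than the full support)
gaussian_kernel <- function(sigma, max_h = Inf) {
  h <- max(1L, min(ceiling(3 * sigma), max_h))
  x <- (-h):h
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Gaussian blur that ignores NA/NaN pixels (normalised convolution).
# Returns NaN where the local valid weight is (numerically) zero.
nan_aware_blur <- function(values, sigma) {
  if (sigma == 0) return(values)
  k <- gaussian_kernel(sigma, max_h = (min(dim(values)) - 1L) %/% 2L)
  valid <- is.finite(values)
  x0 <- values
  x0[!valid] <- 0
  num <- as.matrix(EBImage::filter2(x0, k, boundary = 0))
  den <- as.matrix(EBImage::filter2(valid + 0, k, boundary = 0))
  out <- num / den
  out[den < 1e-12] <- NaN
  out[!valid] <- NaN
  out
}

# well names "A1".."H12" in row-major order
well_names <- function(n_rows, n_cols) {
  paste0(rep(LETTERS[seq_len(n_rows)], each = n_cols),
         rep(seq_len(n_cols), times = n_rows))
}

iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}

# flag codes shared by ratio/analyte maps
FLAG_OK <- 0L
FLAG_CLAMPED <- 1L
FLAG_INVALID <- 2L
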