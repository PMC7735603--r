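#' Map-variable combinations
#'
#' The seven combinations of morphometric variables considered in model
#' selection, in their canonical order.
#'
#' @return named list mapping combo tag to the maps it concatenates.
#' @export
map_combos <- function() {
  list(chr = c("c", "h", "r"),
       c = "c",
       hr = c("h", "r"),
       Nxyz = c("Nx", "Ny", "Nz"),
       Nxy = c("Nx", "Ny"),
       Nxyzr = c("Nx", "Ny", "Nz", "r"),
       chrNxyz = c("c", "h", "r", "Nx", "Ny", "Nz"))
}

#' 2D Fourier transform of a morphometric map
#'
#' Standard unnormalized 2D DFT with the DC component at index (0, 0); both
#' axes are treated as periodic (the angular axis is naturally periodic,
#' and the radial axis is transformed the same way).
#'
#' @param map K x L real matrix (a weighted map).
#' @return K x L complex coefficient matrix of class `spectral_map`.
#' @export
forward_fft <- function(map) {
  m <- as.matrix(map)
  structure(stats::fft(m), class = c("spectral_map", "matrix"))
}

#' Inverse of [forward_fft()]
#'
#' @param coef K x L complex coefficient matrix.
#' @return K x L real matrix.
#' @export
inverse_fft <- function(coef) {
  Re(stats::fft(unclass(coef), inverse = TRUE)) / length(coef)
}

## Indices (0-based frequencies) retained at filter size f for an axis of
## length n: {0, +/-1, ..., +/-f} taken mod n, deduplicated and sorted.
lowpass_indices <- function(n, f) {
  neg <- if (f > 0) (n - f):(n - 1) else integer(0)
  sort(unique(c(0:f, neg) %% n))
}

#' Low-pass selection of Fourier coefficients
#'
#' "Filter size" `f` retains the coefficients whose radial and angular
#' frequency indices both lie in \{0, ±1, ..., ±f\} — the low-frequency
#' block, of size `(2f+1)^2` while `2f+1` is below the grid dimension. At
#' `f = floor(min(K, L)/2)` the whole transform is retained.
#'
#' @param spec a `spectral_map` (or complex matrix).
#' @param f filter size, `0 <= f <= floor(min(K, L)/2)`.
#' @return list with `block` (retained complex submatrix), `u`/`v` (signed
#'   frequency of each retained row/column) and the grid dims; class
#'   `lowpass_block`.
#' @export
lowpass_select <- function(spec, f) {
  m <- unclass(spec)
  K <- nrow(m); L <- ncol(m)
  fmax <- floor(min(K, L) / 2)
  if (f < 0 || f > fmax)
    stopf("filter size f = %d out of range [0, %d] for a %d x %d grid", f, fmax, K, L)
  iu <- lowpass_indices(K, f)
  iv <- lowpass_indices(L, f)
  signed <- function(idx, n) ifelse(idx <= n / 2, idx, idx - n)
  structure(list(block = m[iu + 1L, iv + 1L, drop = FALSE],
                 u = signed(iu, K), v = signed(iv, L),
                 grid_K = K, grid_L = L, f = f),
            class = "lowpass_block")
}

#' Reconstruct a map from a low-pass block
#'
#' Zero-fills the discarded coefficients and inverts the transform; used to
#' inspect what a given filter size retains.
#'
#' @param block a `lowpass_block`.
#' @return K x L real matrix.
#' @export
lowpass_reconstruct <- function(block) {
  m <- matrix(0 + 0i, block$grid_K, block$grid_L)
  iu <- block$u %% block$grid_K
  iv <- block$v %% block$grid_L
  m[iu + 1L, iv + 1L] <- block$block
  inverse_fft(m)
}

## Column phase factors undoing a circular shift by s grid columns of the
## underlying map (content moved forward by s): exp(+2i pi v s / L) per
## angular frequency v.
shift_phase <- function(v, s, L) exp(2i * pi * v * s / L)

## Squared distance profile of block B (rows x angular cols, col freqs v)
## against reference M over all L integer shifts; returns length-L vector
## for s = 0..L-1.
shift_costs <- function(B, M, v, L) {
  const <- sum(Mod(B)^2) + sum(Mod(M)^2)
  cj <- colSums(B * Conj(M)) # per angular column
  s <- 0:(L - 1)
  ph <- exp(2i * pi * outer(v, s) / L) # |v| x L
  const - 2 * Re(colSums(cj * ph))
}

#' Rotational alignment of specimens in Fourier space
#'
#' Generalized-Procrustes-style optimal fitting restricted to rotation
#' about the z axis: each specimen takes the integer column shift (grid
#' rotation) minimizing its squared distance to the current mean block,
#' applied as phase factors `exp(-2i*pi*v*s/L)` on angular frequency `v`;
#' the mean is updated and the procedure iterates until the total distance
#' decreases by less than `tol` or `max_iter` iterations.
#'
#' @param blocks list of complex matrices, one per specimen, with the same
#'   dimensions: rows index (map, radial frequency), columns index angular
#'   frequency.
#' @param v signed angular frequency of each column.
#' @param L angular grid size (number of admissible shifts).
#' @param tol convergence tolerance on the total-distance decrease.
#' @param max_iter iteration cap.
#' @return list with `blocks` (aligned), `shifts` (grid columns, in
#'   \[0, L)), `total_distance`, `iterations`, `converged`.
#' @export
rotational_align <- function(blocks, v, L, tol = 1e-9, max_iter = 100L) {
  n <- length(blocks)
  if (n < 2L) stopf("alignment needs at least 2 specimens")
  shifts <- integer(n)
  aligned <- blocks
  ref <- blocks[[1]]
  total_prev <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mean_blk <- Reduce(`+`, aligned) / n
    if (it == 1L) mean_blk <- ref
    for (i in seq_len(n)) {
      costs <- shift_costs(blocks[[i]], mean_blk, v, L)
      s <- which.min(costs) - 1L
      shifts[i] <- s
      aligned[[i]] <- sweep(blocks[[i]], 2, shift_phase(v, s, L), `*`)
    }
    mean_blk <- Reduce(`+`, aligned) / n
    total <- sum(vapply(aligned, function(b) sum(Mod(b - mean_blk)^2), 0))
    if (total_prev - total < tol) { converged <- TRUE; break }
    total_prev <- total
    if (it >= max_iter) break
  }
  if (!converged)
    warnf("rotational alignment did not converge in %d iterations; returning best fit", max_iter)
  list(blocks = aligned, shifts = shifts, total_distance = total,
       iterations = it, converged = converged)
}

#' Assemble aligned Fourier feature vectors
#'
#' For each specimen: apply area weights (if not yet applied), Fourier
#' transform each map of the chosen combination, retain the low-pass block
#' at filter size `f`, rotationally align all specimens jointly on the
#' concatenated blocks, and concatenate real then imaginary parts per map
#' in combination order.
#'
#' @param mapsets list of `map_set` objects sharing grid dimensions.
#' @param combo one of the tags of [map_combos()].
#' @param f filter size.
#' @param align rotationally align specimens (default TRUE; requires >= 2).
#' @return n x p numeric `feature_set` matrix (rows = specimens) with
#'   attributes `combo`, `f`, `grid`, `shifts`, `groups`, `specimen_ids`.
#' @export
assemble_features <- function(mapsets, combo, f, align = TRUE) {
  combos <- map_combos()
  if (!combo %in% names(combos)) stopf("unknown map combination: %s", combo)
  vars <- combos[[combo]]
  Ks <- vapply(mapsets, `[[`, 0, "grid_K")
  Ls <- vapply(mapsets, `[[`, 0, "grid_L")
  if (length(unique(Ks)) != 1L || length(unique(Ls)) != 1L)
    stopf("specimens have mixed grid dimensions")
  K <- Ks[1]; L <- Ls[1]

  blocks <- vector("list", length(mapsets))
  v_freq <- NULL
  nrow_per_map <- NULL
  for (i in seq_along(mapsets)) {
    ms <- mapsets[[i]]
    if (!ms$weighted) ms <- apply_weights(ms)
    sub <- lapply(vars, function(p) {
      lp <- lowpass_select(forward_fft(ms$maps[[p]]), f)
      v_freq <<- lp$v
      lp$block
    })
    nrow_per_map <- nrow(sub[[1]])
    blocks[[i]] <- do.call(rbind, sub)
  }
  v_all <- v_freq

  shifts <- integer(length(mapsets))
  if (align && length(mapsets) >= 2L) {
    al <- rotational_align(blocks, v_all, L)
    blocks <- al$blocks
    shifts <- al$shifts
  }

  feats <- t(vapply(blocks, function(b) {
    per_map <- lapply(seq_along(vars), function(j) {
      rows <- (j - 1) * nrow_per_map + seq_len(nrow_per_map)
      c(Re(b[rows, , drop = FALSE]), Im(b[rows, , drop = FALSE]))
    })
    unlist(per_map)
  }, numeric(length(vars) * 2 * nrow_per_map * length(v_all))))

  ids <- vapply(mapsets, function(m) m$specimen_id %||% NA_character_, "")
  rownames(feats) <- ids
  structure(feats, class = c("feature_set", "matrix", "array"),
            combo = combo, f = f, grid = c(K, L), shifts = shifts,
            groups = vapply(mapsets, function(m) m$group %||% NA_character_, ""),
            specimen_ids = ids)
}

#' Number of feature dimensions for a combination and filter size
#'
#' `n_maps * 2 * n_u * n_v` where `n_u = min(2f+1, K)` and
#' `n_v = min(2f+1, L)` (real and imaginary parts of the retained block).
#'
#' @param combo combination tag.
#' @param f filter size.
#' @param grid_K,grid_L grid dimensions.
#' @return integer dimension.
#' @export
feature_length <- function(combo, f, grid_K = 300, grid_L = 300) {
  n_maps <- length(map_combos()[[combo]])
  n_maps * 2L * min(2L * f + 1L, grid_K) * min(2L * f + 1L, grid_L)
}
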