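# Brute-force set-arithmetic oracles for the morphology operations, written
# as direct per-voxel loops so they stay independent of the shift-based
# implementations they check.

oracle_dilate <- function(m, offsets) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    hit <- FALSE
    for (r in seq_len(nrow(offsets))) {
      p <- c(i, j, k) - offsets[r, ]
      if (all(p >= 1) && all(p <= d) && m[p[1], p[2], p[3]]) { hit <- TRUE; break }
    }
    out[i, j, k] <- hit
  }
  out
}

oracle_erode <- function(m, offsets) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    keep <- TRUE
    for (r in seq_len(nrow(offsets))) {
      p <- c(i, j, k) + offsets[r, ]
      if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) { keep <- FALSE; break }
    }
    out[i, j, k] <- keep
  }
  out
}

oracle_close <- function(m, offsets) {
  oracle_erode(oracle_dilate(m, offsets), offsets) | m
}

# stack-based 6-connected flood fill
oracle_flood <- function(eligible, seed) {
  d <- dim(eligible)
  visited <- array(FALSE, d)
  if (!eligible[seed[1], seed[2], seed[3]]) return(visited)
  stack <- list(seed)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (r in 1:6) {
      p <- v + offs[r, ]
      if (all(p >= 1) && all(p <= d) && eligible[p[1], p[2], p[3]] &&
          !visited[p[1], p[2], p[3]]) {
        visited[p[1], p[2], p[3]] <- TRUE
        stack[[length(stack) + 1L]] <- p
      }
    }
  }
  visited
}

# connected-component sizes by repeated flood fill
oracle_component_sizes <- function(m) {
  sizes <- integer(0)
  rem <- m
  while (any(rem)) {
    seed <- arrayInd(which(rem)[1], dim(m))
    comp <- oracle_flood(rem, as.integer(seed))
    sizes <- c(sizes, sum(comp))
    rem <- rem & !comp
  }
  sizes
}

oracle_filter_small <- function(m, min_vox) {
  out <- array(FALSE, dim(m))
  rem <- m
  while (any(rem)) {
    seed <- arrayInd(which(rem)[1], dim(m))
    comp <- oracle_flood(rem, as.integer(seed))
    if (sum(comp) >= min_vox) out <- out | comp
    rem <- rem & !comp
  }
  out
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_mask <- function(d, p = 0.35) array(stats::runif(prod(d)) < p, d)

# small phantom-free volumes for unit tests
flat_volume <- function(values, d = NULL, spacing = c(1, 1, 1)) {
  d <- d %||% c(length(values), 1, 1)
  image_volume(array(values, d), spacing = spacing)
}

mask_from <- function(arr, ...) {
  roi_mask(array(arr > 0, dim(arr)), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
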