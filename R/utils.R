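# Internal helpers shared across modules.

# Guo-Hall two-subiteration parallel thinning, driven by the standard
# G123/G123' deletion lookup tables over the 8-neighbour byte
# (bit weights: NW 8, N 4, NE 2, W 16, E 1, SW 32, S 64, SE 128).
# Connectivity-preserving, keeps 2x2 squares and diagonal strokes.
# Returns an integer matrix (0/1); the skeleton is 8-connected.
.g123_del <- local({
  g1 <- c(14, 20, 22, 28, 30, 52, 54, 56, 60, 62, 80, 84, 86, 88, 92, 94,
          112, 116, 118, 120, 124, 126, 193, 208, 209, 212, 216, 217, 220,
          224, 225, 240, 241, 244, 248, 249, 252)
  g2 <- c(5, 7, 13, 14, 15, 28, 29, 30, 31, 65, 67, 69, 71, 77, 79, 97, 99,
          101, 103, 131, 133, 135, 141, 143, 157, 159, 193, 195, 197, 199,
          205, 207, 224, 225, 227, 229, 231)
  lut1 <- logical(256); lut1[g1 + 1L] <- TRUE
  lut2 <- logical(256); lut2[g2 + 1L] <- TRUE
  list(lut1, lut2)
})

zs_thin <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  if (sum(m) < 3L) return(m)
  P <- matrix(0L, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
  repeat {
    changed <- FALSE
    for (lut in .g123_del) {
      idx <- 8L * sh(-1L, -1L) + 4L * sh(-1L, 0L) + 2L * sh(-1L, 1L) +
        16L * sh(0L, -1L) + 1L * sh(0L, 1L) +
        32L * sh(1L, -1L) + 64L * sh(1L, 0L) + 128L * sh(1L, 1L)
      cur <- P[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
      cond <- cur == 1L & lut[idx + 1L]
      if (any(cond)) {
        cur[cond] <- 0L
        P[2:(nr + 1L), 2:(nc + 1L)] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# 8-connected component labelling by breadth-first flood fill on shifted
# index sets. Returns an integer matrix with 0 background, components 1..k.
label_components8 <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  todo <- which(m & lab == 0L)
  offs <- as.integer(c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1))
  rowof <- function(idx) ((idx - 1L) %% nr) + 1L
  while (length(todo)) {
    seed <- todo[1L]
    nextlab <- nextlab + 1L
    frontier <- seed
    lab[seed] <- nextlab
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + offs
      rsrc <- rep(rowof(frontier), each = 8L)
      ok <- cand >= 1L & cand <= nr * nc & abs(rowof(cand) - rsrc) <= 1L
      cand <- unique(cand[ok])
      cand <- cand[m[cand] & lab[cand] == 0L]
      lab[cand] <- nextlab
      frontier <- cand
    }
    todo <- which(m & lab == 0L)
  }
  lab
}

# FNV-1a hash over a character string; deterministic config fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
    # multiply by the FNV prime 16777619 = 403 + 2^24, mod 2^32, split to
    # stay within double precision
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Positive scalar check used by input validation throughout.
stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
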