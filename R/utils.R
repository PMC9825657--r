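# internal helpers shared across modules

# Deterministic substream seed from a root seed and a stage label.
# Mersenne-Twister streams initialised from seeds in arithmetic
# progression are measurably correlated, so the derivation must be a
# nonlinear integer hash, not an affine map: seeds that differ by a
# constant stride would otherwise yield correlated simulations (and, for
# example, an inflated type-I error across replicate experiments).
# splitmix-style 32-bit mixing, done in doubles with explicit mod-2^32
# arithmetic because R has no unsigned 32-bit integers.
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
}

mulmod32 <- function(a, b) {
  lo <- b %% 65536
  hi <- (b - lo) / 65536
  (((a * hi) %% 4294967296) * 65536 + a * lo) %% 4294967296
}

mix32 <- function(x) {
  x <- xor32(x, x %/% 65536)
  x <- mulmod32(x, 2246822519)
  x <- xor32(x, x %/% 8192)
  x <- mulmod32(x, 3266489917)
  xor32(x, x %/% 65536)
}

derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  x <- as.numeric(seed) %% 4294967296
  x <- mix32((x + 2654435769) %% 4294967296)
  for (ch in utf8ToInt(label)) {
    x <- mix32((x + ch * 2654435769) %% 4294967296)
  }
  as.integer(x %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# physical length (um or nm) to pixels
um_to_px <- function(um, pixel_size_nm) um * 1000 / pixel_size_nm
nm_to_px <- function(nm, pixel_size_nm) nm / pixel_size_nm

as_logical_mask <- function(x) {
  if (is.logical(x)) return(x)
  m <- x > 0.5
  dim(m) <- dim(x)
  m
}

stopifnot_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must share dimensions (%s vs %s)", what,
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

# Otsu threshold on a numeric vector (histogram-based, 256 bins).
# Returns NA when the values are constant (threshold undefined).
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Exact Euclidean distance (in pixels) from every pixel to the nearest TRUE
# pixel of `mask`. Thin wrapper over EBImage's exact EDT.
distance_to_mask <- function(mask) {
  if (!any(mask)) abort("distance_to_mask: mask is empty")
  storage.mode(mask) <- "double"
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  m <- EBImage::imageData(d)
  dim(m) <- dim(mask)
  m
}

# 8-connected component labelling of a logical matrix. Returns an integer
# matrix of labels (0 = background). EBImage::bwlabel is 4-connected, which
# splits diagonally-touching blobs, so labelling is done over the
# 8-neighbour adjacency graph of foreground pixels.
label_components_8 <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  lab <- matrix(0L, dm[1], dm[2])
  if (length(idx) == 0L) return(lab)
  nr <- dm[1]
  pos <- match(seq_len(prod(dm)), idx)  # linear index -> vertex id (NA if bg)
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  k <- 1L
  for (shift in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row_i + shift[1]; c2 <- col_i + shift[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= dm[2]
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    v2 <- pos[nb]
    keep <- !is.na(v2)
    if (any(keep)) {
      edges[[k]] <- cbind(pos[idx[ok][keep]], v2[keep])
      k <- k + 1L
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# bilinear interpolation of matrix `m` at (possibly fractional) 1-based
# (row, col) coordinates; vectors r and c of equal length
bilinear_interp <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(r), 1), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
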