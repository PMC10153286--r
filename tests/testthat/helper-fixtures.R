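# Shared fixtures and independent oracles, built in code at test time.

# Even-odd point-in-polygon oracle, independent of the package rasterizer.
# Returns TRUE for points strictly inside the closed polygon (px, py).
polygon_contains <- function(px, py, qx, qy) {
  k <- length(px)
  inside <- rep(FALSE, length(qx))
  j <- k
  for (i in seq_len(k)) {
    crosses <- ((py[i] > qy) != (py[j] > qy))
    xi <- px[i] + (qy - py[i]) * (px[j] - px[i]) /
      ifelse(py[j] == py[i], Inf, py[j] - py[i])
    inside <- xor(inside, crosses & (qx < xi))
    j <- i
  }
  inside
}

# rectangular strip geometry: half-width w_px pixels along x, spanning the
# grid in y with a 2-pixel margin
make_strip_geometry <- function(n, pixel_size, w_px) {
  ind <- matrix(0, n, n)
  ind[(n / 2 - w_px + 1):(n / 2 + w_px), 3:(n - 2)] <- 1
  cell_geometry(ind, pixel_size)
}

make_disk_geometry <- function(radius_um, n, pixel_size) {
  prof <- generate_profile(shape_descriptor(0, radius_um, 0, 0), seed = 1)
  rasterize_profile(prof, n, pixel_size)
}

# small uniform-stiffness corpus cached across test files
tiny_corpus <- local({
  cache <- NULL
  function(count = 12, n = 32L, seed = 7L) {
    key <- paste(count, n, seed)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    co <- build_corpus(count, seed = seed, n = n,
                       d_ranges = list(ns = c(2, 5), rbar = c(40, 120),
                                       rs = c(0, 0.25), sigma_s = c(2, 6)))
    attr(co, "key") <- key
    cache <<- co
    co
  }
})

expect_traction_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a$components - b$components)), tol)
}
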