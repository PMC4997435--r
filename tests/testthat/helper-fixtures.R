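# Deterministic fixtures and independent oracles shared across the suite.

# random space-time sample cloud in a unit-ish box
make_cloud <- function(n, seed, days = 10L, value_fn = NULL) {
  withr::with_seed(seed, {
    s <- data.frame(
      site_id = sprintf("s%03d", seq_len(n)),
      x = runif(n),
      y = runif(n),
      t = sample.int(days, n, replace = TRUE))
    s$w <- if (is.null(value_fn)) runif(n, 5, 20) else
      value_fn(s$x, s$y, s$t)
    s
  })
  }

rand_mesh <- function(n = 40, seed = 1, cscale = 0.1, days = 10L,
                      value_fn = NULL) {
  s <- make_cloud(n, seed, days = days, value_fn = value_fn)
  sc <- time_scale(cscale)
  list(samples = st_samples(s), scale = sc,
       mesh = build_mesh(st_samples(s), sc))
}

# brute-force IDW oracle: rank all samples by space-time distance (stable
# tie-break on sample index), then apply the inverse-distance weights
# directly
brute_idw <- function(samples, queries, N, p, scale) {
  S <- cbind(samples$x, samples$y, scale$c * samples$t)
  vapply(seq_len(nrow(queries)), function(i) {
    q <- c(queries$x[i], queries$y[i], scale$c * queries$t[i])
    d <- sqrt((S[, 1] - q[1])^2 + (S[, 2] - q[2])^2 + (S[, 3] - q[3])^2)
    ord <- order(d, seq_along(d))[seq_len(N)]
    dn <- d[ord]
    wv <- samples$w[ord]
    if (any(dn == 0)) return(mean(wv[dn == 0]))
    lam <- (1 / dn)^p
    sum(lam * wv) / sum(lam)
  }, numeric(1))
}

# loop-based error statistics oracle (no vectorization)
loop_stats <- function(I, O) {
  n <- length(I)
  sae <- 0; sse <- 0; sre <- 0
  for (i in seq_len(n)) {
    sae <- sae + abs(I[i] - O[i])
    sse <- sse + (I[i] - O[i])^2
    sre <- sre + abs(I[i] - O[i]) / O[i]
  }
  mae <- sae / n; mse <- sse / n
  obar <- 0
  for (i in seq_len(n)) obar <- obar + O[i]
  obar <- obar / n
  sso <- 0
  for (i in seq_len(n)) sso <- sso + (O[i] - obar)^2
  mseo <- sso / n
  r2 <- if (mseo == 0) { if (mse == 0) 1 else 0 } else
    max(0, 1 - mse / mseo)
  c(mae = mae, mse = mse, rmse = sqrt(mse), mare = sre / n, r2cv = r2)
}

# brute-force containment over every tetrahedron of a mesh
brute_inside <- function(mesh, q, tol = 1e-9) {
  for (ti in seq_len(nrow(mesh$tets))) {
    tet <- mesh$points[mesh$tets[ti, ], , drop = FALSE]
    if (mesh$degenerate[ti]) next
    w <- tryCatch(shape_weights(tet, q), error = function(e) NULL)
    if (!is.null(w) && min(w) >= -tol) return(ti)
  }
  NA_integer_
}

# scipy.spatial oracle (independent geometry implementation): returns the
# Delaunay simplices as sorted index keys and the convex hull volume
scipy_delaunay <- function(points) {
  fp <- tempfile(fileext = ".txt")
  fo <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fp, fo)), add = TRUE)
  utils::write.table(points, fp, row.names = FALSE, col.names = FALSE)
  code <- paste0(
    "import numpy as np\n",
    "from scipy.spatial import Delaunay, ConvexHull\n",
    sprintf("P = np.loadtxt(%s)\n", deparse(fp)),
    "d = Delaunay(P); h = ConvexHull(P)\n",
    "keys = sorted('-'.join(map(str, sorted(s + 1))) for s in d.simplices)\n",
    sprintf(
      "open(%s, 'w').write(repr(h.volume) + '\\n' + '\\n'.join(keys) + '\\n')\n",
      deparse(fo)))
  res <- system2("python", c("-c", shQuote(code)), stdout = TRUE,
                 stderr = TRUE)
  lines <- readLines(fo)
  list(hull_volume = as.numeric(lines[1]), keys = lines[-1])
}

tet_keys <- function(tets) {
  sort(apply(tets, 1, function(r) paste(sort(r), collapse = "-")))
}
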