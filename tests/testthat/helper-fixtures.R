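# shared fixture builders (everything generated in code; no binary data)

# a concave ("L"-shaped) polygon for containment tests
l_polygon <- function() {
  polygon_region(rbind(c(0, 0), c(4, 0), c(4, 1), c(1, 1), c(1, 4), c(0, 4)),
                 "ki67_region")
}

# random simple polygon: radial star around the origin
random_star_polygon <- function(n = 12, rmin = 1, rmax = 5) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  polygon_region(cbind(r * cos(th), r * sin(th)), "tumor_bed", check = FALSE)
}

# winding-number containment oracle (independent of the ray-casting path)
winding_inside <- function(px, py, v) {
  n <- nrow(v)
  ang <- 0
  for (k in seq_len(n)) {
    a <- c(v[k, 1] - px, v[k, 2] - py)
    b <- c(v[(k %% n) + 1, 1] - px, v[(k %% n) + 1, 2] - py)
    ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(ang) > pi  # ~2*pi inside, ~0 outside
}

# minimal annotation: unit-square bed scaled up, optional residual + marks
toy_annotation <- function(case_id = "c1", block_id = "b1",
                           residual_frac = 0.25, n_marks = 0, p_pos = 0.5,
                           pck = 100L) {
  bed <- polygon_region(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
                        "tumor_bed")
  regs <- list(bed)
  if (residual_frac > 0) {
    s <- 100 * sqrt(residual_frac)
    regs <- c(regs, list(polygon_region(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)),
                                        "residual_tumor")))
  }
  marks <- if (n_marks > 0)
    cell_marks(stats::runif(n_marks, 0, 100), stats::runif(n_marks, 0, 100),
               stats::runif(n_marks) < p_pos)
  else cell_marks(numeric(0), numeric(0), logical(0))
  block_annotation(case_id, block_id, regions = regs, marks = marks,
                   pck_tumor_cell_count = pck)
}

# brute-force exact p for small r x c tables: enumerate cell-by-cell over
# expand.grid of feasible values (independent of the package's recursion)
brute_force_exact_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  r <- nrow(tab); cc <- ncol(tab)
  free <- expand.grid(rep(list(0:max(rs)), (r - 1) * (cc - 1)))
  lp_of <- function(m) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(n + 1) - sum(lgamma(m + 1))
  lobs <- lp_of(tab)
  total <- 0
  for (i in seq_len(nrow(free))) {
    m <- matrix(0, r, cc)
    m[seq_len(r - 1), seq_len(cc - 1)] <- as.numeric(free[i, ])
    m[r, seq_len(cc - 1)] <- cs[seq_len(cc - 1)] - colSums(m[, seq_len(cc - 1), drop = FALSE])[seq_len(cc - 1)]
    m[, cc] <- rs - rowSums(m)
    if (any(m < 0)) next
    lp <- lp_of(m)
    if (lp <= lobs + log(1 + 1e-7)) total <- total + exp(lp)
  }
  total
}
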