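#' Synthetic BIR2-like reference fold
#'
#' A one-bead-per-residue reference geometry for residues 163-234 of the
#' XIAP BIR2 domain, constructed by distance-geometry optimization rather
#' than taken from deposited coordinates (it is a synthetic stand-in, not the
#' crystallographic structure). The target distance set encodes the domain's
#' architecture: two N-terminal helices (163-168, 181-186) in contact through
#' the 166-185 pair, the RIP2-binding loops 174-182 and 205-215, an
#' antiparallel beta pair (198-200 and 206-208) joined by the 201-204 turn,
#' the buried 188 position stapled to 201 and 229, a C-terminal helix
#' (216-225), the CCHC Zn-finger quartet (200, 203, 220, 227) drawn into a
#' pocket, and pairwise clustering of the 11 hydrophobic-core residues.
#'
#' The optimization is deterministic (fixed internal seed for the initial
#' chain, then L-BFGS-B with analytic gradients) and the result is cached for
#' the session.
#'
#' @return List with `resid` (integer vector 163:234) and `coords`
#'   (72 x 3 matrix, Angstrom).
#' @export
bir2_reference <- function() {
  if (!is.null(the$reference)) return(the$reference)
  resid <- 163:234
  n <- length(resid)
  idx <- function(r) r - 162L

  tg <- list()  # rows: i, j, dist, weight (residue numbering)
  add <- function(i, j, d, w) tg[[length(tg) + 1]] <<- c(i, j, d, w)

  for (r in 163:233) add(r, r + 1, 3.8, 10)              # virtual bonds
  for (seg in list(163:168, 181:186, 216:225)) {          # helices
    for (r in seg) {
      if ((r + 2) %in% seg) add(r, r + 2, 5.4, 3)
      if ((r + 3) %in% seg) add(r, r + 3, 5.0, 3)
    }
  }
  for (seg in list(198:200, 206:208)) {                   # extended strands
    add(seg[1], seg[3], 6.7, 3)
  }
  # helix-helix contact (166-185 hydrogen-bond surrogate and neighbours)
  add(166, 185, 6.0, 3); add(164, 184, 6.5, 2); add(167, 182, 6.5, 2)
  add(163, 187, 7.0, 1)
  # antiparallel beta ladder 198-200 vs 206-208
  add(198, 208, 5.0, 3); add(199, 207, 5.0, 3); add(200, 206, 5.0, 3)
  add(199, 208, 6.4, 1); add(199, 206, 6.4, 1)
  # 201-204 turn and the buried 188 staples
  add(201, 204, 5.5, 2); add(201, 203, 5.4, 1); add(202, 204, 5.4, 1)
  add(188, 201, 6.0, 2); add(188, 229, 6.5, 2); add(187, 201, 6.5, 1)
  # CCHC Zn-finger pocket: all pairs among 200, 203, 220, 227
  zn <- c(200, 203, 220, 227)
  for (a in 1:3) for (b in (a + 1):4) add(zn[a], zn[b], 6.5, 2)
  # hydrophobic-core clustering
  core_pairs <- list(c(170, 184), c(170, 173), c(173, 179), c(177, 210),
                     c(179, 207), c(184, 189), c(187, 198), c(189, 198),
                     c(189, 207), c(207, 210), c(210, 216), c(177, 216),
                     c(173, 210))
  for (p in core_pairs) add(p[1], p[2], 6.5, 2)

  tg <- do.call(rbind, tg)
  ti <- idx(tg[, 1]); tj <- idx(tg[, 2]); td <- tg[, 3]; tw <- tg[, 4]

  # excluded-volume pair list: all |i-j| >= 2
  ev <- which(outer(seq_len(n), seq_len(n), function(a, b) b - a >= 2),
              arr.ind = TRUE)
  ei <- ev[, 1]; ej <- ev[, 2]
  d_min <- 4.0; w_ev <- 5; w_rg <- 0.5; rg_max <- 11

  objective <- function(par) {
    x <- matrix(par, ncol = 3)
    dv <- x[ti, ] - x[tj, ]
    dd <- sqrt(rowSums(dv^2))
    e1 <- sum(tw * (dd - td)^2)
    evv <- x[ei, ] - x[ej, ]
    ed <- sqrt(rowSums(evv^2))
    pen <- pmax(d_min - ed, 0)
    e2 <- w_ev * sum(pen^2)
    cx <- sweep(x, 2, colMeans(x))
    rg <- sqrt(mean(rowSums(cx^2)))
    e3 <- w_rg * max(rg - rg_max, 0)^2
    e1 + e2 + e3
  }
  gradient <- function(par) {
    x <- matrix(par, ncol = 3)
    g <- matrix(0, n, 3)
    dv <- x[ti, ] - x[tj, ]
    dd <- sqrt(rowSums(dv^2))
    coef <- 2 * tw * (dd - td) / dd
    gi <- dv * coef
    for (a in 1:3) {
      g[, a] <- g[, a] + tapply(c(gi[, a], -gi[, a]), c(ti, tj), sum)[
        as.character(seq_len(n))] %replace_na% 0
    }
    evv <- x[ei, ] - x[ej, ]
    ed <- sqrt(rowSums(evv^2))
    act <- ed < d_min
    if (any(act)) {
      coef2 <- -2 * w_ev * (d_min - ed[act]) / ed[act]
      gv <- evv[act, , drop = FALSE] * coef2
      for (a in 1:3) {
        g[, a] <- g[, a] +
          (tapply(c(gv[, a], -gv[, a]), c(ei[act], ej[act]), sum)[
            as.character(seq_len(n))] %replace_na% 0)
      }
    }
    cx <- sweep(x, 2, colMeans(x))
    rg <- sqrt(mean(rowSums(cx^2)))
    if (rg > rg_max) {
      g <- g + 2 * w_rg * (rg - rg_max) / (n * rg) * cx
    }
    as.numeric(g)
  }

  x0 <- local_rng(163L, {
    x <- matrix(0, n, 3)
    for (i in 2:n) {
      step <- rnorm(3)
      step <- step / sqrt(sum(step^2)) * 3.8
      # weak pull toward the origin keeps the starting chain compact
      pull <- -0.15 * x[i - 1, ] / max(sqrt(sum(x[i - 1, ]^2)), 1)
      d <- step + pull * 3.8
      x[i, ] <- x[i - 1, ] + d / sqrt(sum(d^2)) * 3.8
    }
    x
  })

  opt <- stats::optim(as.numeric(x0), objective, gradient, method = "L-BFGS-B",
                      control = list(maxit = 3000, factr = 1e4))
  coords <- matrix(opt$par, ncol = 3)
  rownames(coords) <- resid
  the$reference <- list(resid = resid, coords = coords)
  the$reference
}

# vectorized NA replacement used by the gradient accumulators
`%replace_na%` <- function(x, value) {
  x[is.na(x)] <- value
  x
}
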