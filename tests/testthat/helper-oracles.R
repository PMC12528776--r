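# Independent oracles: naive per-pixel/per-voxel decomposition, brute-force
# Cox partial likelihood, and a direct empirical ROC AUC. These deliberately
# use plain loops and none of the package's vectorised code paths.

oracle_decompose <- function(airway, lung, config = decomposition_config()) {
  tr <- locate_trachea(airway, config)
  lungs <- split_lungs(lung, tr$carina_mm)
  grid <- airway$grid
  sp <- grid$spacing
  nz <- grid$shape[1]; ny <- grid$shape[2]; nx <- grid$shape[3]
  nt <- airway$voxels & !tr$trachea
  nt_comp <- tr$component & !tr$trachea

  side_of_voxel <- function(z, y, x) {
    if (lungs$right$voxels[z, y, x]) return(-1L)
    if (lungs$left$voxels[z, y, x]) return(1L)
    if ((x - 1) * sp[3] < tr$carina_mm[3]) -1L else 1L
  }

  # pixel lists
  pix <- list()
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    col <- which(nt[, y, x])
    if (!length(col)) next
    sides <- vapply(col, function(z) side_of_voxel(z, y, x), integer(1))
    s <- sum(sides)
    side <- if (s != 0) sign(s) else
      (if ((x - 1) * sp[3] < tr$carina_mm[3]) -1L else 1L)
    in_comp <- any(nt_comp[, y, x])
    pix[[length(pix) + 1L]] <- list(y = y, x = x, side = side, in_comp = in_comp)
  }

  D <- matrix(NA_real_, ny, nx)
  for (s in c(-1L, 1L)) {
    ref <- Filter(function(p) p$side == s && p$in_comp, pix)
    all_s <- Filter(function(p) p$side == s, pix)
    if (!length(all_s)) next
    if (!length(ref)) ref <- all_s
    cy <- mean(vapply(ref, function(p) (p$y - 1) * sp[2], numeric(1)))
    cx <- mean(vapply(ref, function(p) (p$x - 1) * sp[3], numeric(1)))
    dmax <- 0
    for (p in ref) {
      d <- sqrt(((p$y - 1) * sp[2] - cy)^2 + ((p$x - 1) * sp[3] - cx)^2)
      if (d > dmax) dmax <- d
    }
    for (p in all_s) {
      d <- sqrt(((p$y - 1) * sp[2] - cy)^2 + ((p$x - 1) * sp[3] - cx)^2)
      D[p$y, p$x] <- if (dmax > 0) min(d / dmax, 1) else 0
    }
  }

  classify1 <- function(v) {
    if (v >= config$t_terminal) 4L else if (v >= config$t_small) 3L else 2L
  }

  # tree height from the largest component
  zc <- tr$carina_mm[1]
  height <- 0
  for (z in seq_len(nz)) if (any(nt_comp[z, , ]))
    height <- max(height, (z - 1) * sp[1] - zc)

  labels <- array(0L, dim = grid$shape)
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (tr$trachea[z, y, x]) { labels[z, y, x] <- 1L; next }
    if (!nt[z, y, x]) next
    v <- D[y, x]
    cls <- classify1(v)
    if (config$revision == "vertical-max" && height > 0) {
      h <- min(max(((z - 1) * sp[1] - zc) / height, 0), 1)
      cls <- max(cls, classify1(max(v, h)))
    }
    labels[z, y, x] <- cls
  }
  list(D = D, labels = labels, height = height)
}

# brute-force Cox partial log-likelihood for a single covariate (no ties)
oracle_cox_loglik <- function(time, event, x) {
  function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
}

# empirical ROC AUC of cases-by-t vs survivors-past-t (no censoring)
oracle_empirical_auc <- function(time, marker, horizon) {
  cases <- marker[time <= horizon]
  ctrls <- marker[time > horizon]
  num <- 0
  for (m in cases) num <- num + sum(m > ctrls) + 0.5 * sum(m == ctrls)
  num / (length(cases) * length(ctrls))
}
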