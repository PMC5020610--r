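# Scalar reaction coordinates, 1D/2D probability surfaces, free-energy
# surfaces with basin detection, convergence diagnostics and the
# replica-exchange temperature ladder.

GAS_R_KCAL <- 1.987e-3  # kcal/(mol K)

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_cm|^2 / sum_i m_i )` with masses by
#' element.
#'
#' @param x An [ensemble()] or [conformation()].
#' @param selection Atom indices; default all peptide heavy atoms (the
#'   dimer without ligands or hydrogens).
#' @return Rg in nm; one value per frame for an ensemble.
#' @export
radius_of_gyration <- function(x, selection = NULL) {
  single <- inherits(x, "conformation")
  if (single) x <- ensemble(x$topology, list(x$xyz))
  top <- x$topology
  if (is.null(selection)) {
    selection <- select_atoms(top, class = c("main_chain", "side_chain"),
                              heavy = TRUE)
  }
  if (!length(selection)) stop("empty selection")
  m <- atom_masses(top)[selection]
  m <- m / sum(m)
  out <- vapply(x$frames, function(xyz) {
    r <- xyz[selection, , drop = FALSE]
    cm <- colSums(r * m)
    sqrt(sum(m * rowSums(sweep(r, 2, cm)^2)))
  }, numeric(1))
  if (single) out[1] else out
}

#' Two-dimensional free-energy surface
#'
#' Bins weighted samples of two reaction coordinates into a 2D histogram
#' P(x, y) and returns `G = -RT ln P`, shifted so the lowest unmasked bin
#' is 0; empty bins are masked (`NA`). R = 1.987e-3 kcal/(mol K), so G is
#' in kcal/mol.
#'
#' @param x,y Numeric sample vectors (equal length, >= 1).
#' @param weights Sample weights (default uniform).
#' @param xbreaks,ybreaks Bin edges; alternatively `bins` (count or
#'   length-2) builds equal-width edges over the sample range.
#' @param bins Number of bins per axis when explicit breaks are absent.
#' @param temperature_K Temperature, default 310.
#' @return Object of class `"fes_grid"`; `tidy()` gives the long form.
#' @export
fes2d <- function(x, y, weights = NULL, xbreaks = NULL, ybreaks = NULL,
                  bins = 32, temperature_K = 310) {
  if (length(x) != length(y) || !length(x)) {
    stop("x and y must be nonempty vectors of equal length")
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  weights <- weights / sum(weights)
  bins <- rep_len(bins, 2)
  mkbreaks <- function(v, nb) {
    r <- range(v)
    if (diff(r) <= 0) stop("zero-width bin range; supply explicit breaks")
    seq(r[1], r[2], length.out = nb + 1)
  }
  if (is.null(xbreaks)) xbreaks <- mkbreaks(x, bins[1])
  if (is.null(ybreaks)) ybreaks <- mkbreaks(y, bins[2])
  if (any(diff(xbreaks) <= 0) || any(diff(ybreaks) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  bx <- cut(x, xbreaks, include.lowest = TRUE, labels = FALSE)
  by <- cut(y, ybreaks, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bx) & !is.na(by)
  P <- matrix(0, length(xbreaks) - 1, length(ybreaks) - 1)
  for (k in which(keep)) P[bx[k], by[k]] <- P[bx[k], by[k]] + weights[k]
  P <- P / sum(P)
  RT <- GAS_R_KCAL * temperature_K
  G <- -RT * log(P)
  G[!is.finite(G)] <- NA
  shift <- min(G, na.rm = TRUE)
  G <- G - shift
  structure(list(G = G, P = P, xbreaks = xbreaks, ybreaks = ybreaks,
                 xmid = (xbreaks[-1] + xbreaks[-length(xbreaks)]) / 2,
                 ymid = (ybreaks[-1] + ybreaks[-length(ybreaks)]) / 2,
                 temperature_K = temperature_K, R = GAS_R_KCAL,
                 shift = shift),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid> ", nrow(x$G), " x ", ncol(x$G), " bins at ",
      x$temperature_K, " K; ", sum(!is.na(x$G)), " populated\n", sep = "")
  invisible(x)
}

#' @rdname fes2d
#' @param ... Unused.
#' @export
tidy.fes_grid <- function(x, ...) {
  g <- x
  grid <- tidyr::expand_grid(xi = seq_along(g$xmid), yi = seq_along(g$ymid))
  tibble::tibble(x = g$xmid[grid$xi], y = g$ymid[grid$yi],
                 G = g$G[cbind(grid$xi, grid$yi)],
                 P = g$P[cbind(grid$xi, grid$yi)])
}

#' Locate free-energy basins
#'
#' Finds local minima of a free-energy surface over 8-neighborhoods and
#' filters them by topographic prominence: a minimum survives only if the
#' lowest saddle connecting it to any deeper minimum lies at least
#' `depth_threshold` kcal/mol above it (persistence merging). The deepest
#' minimum always survives. Basins are reported at bin centers, deepest
#' first.
#'
#' @param grid A `"fes_grid"` from [fes2d()].
#' @param depth_threshold Minimum basin depth (kcal/mol), default 0.5.
#' @return Tibble with `x_center`, `y_center`, `G` and `prominence`
#'   (`Inf` for the global minimum).
#' @export
find_basins <- function(grid, depth_threshold = 0.5) {
  G <- grid$G
  cells <- which(!is.na(G))
  if (!length(cells)) stop("all bins of the surface are masked")
  ord <- cells[order(G[cells])]
  nr <- nrow(G); nc <- ncol(G)
  comp <- rep(NA_integer_, nr * nc)   # cell -> component root id
  root_min <- c(); root_cell <- c()   # per root: min G, min cell
  parent <- integer(0)
  findr <- function(r) {
    while (parent[r] != r) r <- parent[r]
    r
  }
  recorded <- list()
  for (cell in ord) {
    i <- (cell - 1) %% nr + 1; j <- (cell - 1) %/% nr + 1
    nbr <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        cc <- (jj - 1) * nr + ii
        if (!is.na(comp[cc])) nbr <- c(nbr, findr(comp[cc]))
      }
    }
    nbr <- unique(nbr)
    if (!length(nbr)) {
      parent[length(parent) + 1] <- length(parent) + 1
      root_min[length(parent)] <- G[cell]
      root_cell[length(parent)] <- cell
      comp[cell] <- length(parent)
    } else {
      surv <- nbr[which.min(root_min[nbr])]
      for (r in setdiff(nbr, surv)) {
        prom <- G[cell] - root_min[r]
        if (prom >= depth_threshold) {
          recorded[[length(recorded) + 1]] <-
            c(cell = root_cell[r], G = root_min[r], prom = prom)
        }
        parent[r] <- surv
      }
      comp[cell] <- surv
    }
  }
  # surviving roots are basins (the deepest of each final component)
  final_roots <- which(parent == seq_along(parent))
  for (r in final_roots) {
    recorded[[length(recorded) + 1]] <-
      c(cell = root_cell[r], G = root_min[r], prom = Inf)
  }
  tb <- purrr::map_dfr(recorded, function(b) {
    cell <- b[["cell"]]
    i <- (cell - 1) %% nr + 1; j <- (cell - 1) %/% nr + 1
    tibble::tibble(x_center = grid$xmid[i], y_center = grid$ymid[j],
                   G = b[["G"]], prominence = b[["prom"]])
  })
  dplyr::arrange(tb, .data$G)
}

# Jensen-Shannon distance (base 2, in [0, 1]) between two histograms
.js_distance <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  sqrt(pmax(0, 0.5 * kl(p, m) + 0.5 * kl(q, m)))
}

BUILTIN_METRICS <- c("rg", "hbonds", "helix_content", "sheet_content",
                     "coil_content")

.metric_values <- function(ens, metric) {
  if (is.function(metric)) return(metric(ens))
  switch(metric,
    rg = radius_of_gyration(ens),
    hbonds = suppressWarnings(hbond_count(ens)),
    helix_content = ,
    sheet_content = ,
    coil_content = {
      cls <- switch(metric, helix_content = c("H", "G", "I"),
                    sheet_content = "E", coil_content = "C")
      a <- assign_ss(ens)
      rowMeans(matrix(a$classes %in% cls, nrow = nrow(a$classes)))
    },
    stop("unknown metric: ", metric))
}

#' Split-half convergence diagnostic
#'
#' Splits an ensemble into its two contiguous halves, computes each
#' metric's distribution in both halves over a common binning, and reports
#' the Jensen-Shannon distance (base 2, in [0, 1]) between the half
#' distributions - near 0 for converged sampling, near 1 for disjoint
#' halves.
#'
#' @param ens An [ensemble()] with at least 4 frames.
#' @param metrics Character vector of built-in metrics (`"rg"`,
#'   `"hbonds"`, `"helix_content"`, `"sheet_content"`, `"coil_content"`)
#'   and/or a named list of functions `ensemble -> per-frame numeric`.
#' @param bins Number of histogram bins (default 20).
#' @return Tibble with `metric` and `jsd`; metrics that fail on the
#'   topology are skipped with a warning.
#' @export
split_half_convergence <- function(ens, metrics = c("rg", "hbonds"),
                                   bins = 20) {
  if (n_frames(ens) < 4) stop("need at least 4 frames")
  if (is.character(metrics)) metrics <- stats::setNames(as.list(metrics), metrics)
  half <- floor(n_frames(ens) / 2)
  e1 <- subset_frames(ens, seq_len(half))
  e2 <- subset_frames(ens, (half + 1):n_frames(ens))
  out <- purrr::imap_dfr(metrics, function(m, name) {
    v1 <- try(.metric_values(e1, m), silent = TRUE)
    v2 <- try(.metric_values(e2, m), silent = TRUE)
    if (inherits(v1, "try-error") || inherits(v2, "try-error")) {
      warning("metric '", name, "' undefined for this ensemble; skipped",
              call. = FALSE)
      return(tibble::tibble())
    }
    r <- range(c(v1, v2))
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    breaks <- seq(r[1], r[2], length.out = bins + 1)
    h1 <- graphics::hist(v1, breaks = breaks, plot = FALSE)$counts
    h2 <- graphics::hist(v2, breaks = breaks, plot = FALSE)$counts
    tibble::tibble(metric = name, jsd = .js_distance(h1, h2))
  })
  out
}

#' Replica round-trip counts
#'
#' For each replica's temperature-index time series, counts completed
#' bottom -> top -> bottom round trips through the temperature ladder - a
#' standard replica-exchange mixing diagnostic.
#'
#' @param series Integer matrix (time x replicas), or a list of integer
#'   vectors, of 0-based temperature-ladder indices.
#' @param n_replicas Ladder size; default inferred as `max(series) + 1`.
#' @return Integer vector of round-trip counts, one per replica.
#' @export
replica_traversal <- function(series, n_replicas = NULL) {
  if (is.matrix(series)) series <- lapply(seq_len(ncol(series)), function(j) series[, j])
  allv <- unlist(series)
  if (is.null(n_replicas)) n_replicas <- max(allv) + 1
  if (any(allv < 0 | allv >= n_replicas)) {
    stop("temperature index out of range [0, ", n_replicas - 1, "]")
  }
  top <- n_replicas - 1
  vapply(series, function(s) {
    trips <- 0L
    state <- "seek_bottom"
    for (v in s) {
      if (state == "seek_bottom" && v == 0) state <- "seek_top"
      else if (state == "seek_top" && v == top) state <- "returning"
      else if (state == "returning" && v == 0) {
        trips <- trips + 1L
        state <- "seek_top"
      }
    }
    trips
  }, integer(1))
}

#' Geometric replica-exchange temperature ladder
#'
#' `T_i = T_min (T_max/T_min)^(i/(n-1))`, the constant-ratio ladder that
#' yields approximately uniform exchange acceptance for a system with
#' temperature-independent heat capacity. Endpoints are exact.
#'
#' @param t_min,t_max Ladder endpoints in kelvin (`t_min < t_max`).
#' @param n_replicas Number of replicas (>= 2); e.g. 48 replicas over
#'   306-409 K for an explicit-solvent peptide-dimer system.
#' @return Strictly increasing numeric vector of length `n_replicas`.
#' @export
temperature_ladder <- function(t_min, t_max, n_replicas) {
  if (!(t_min < t_max)) stop("t_min must be < t_max")
  if (n_replicas < 2) stop("need at least 2 replicas")
  i <- seq_len(n_replicas) - 1
  temps <- t_min * (t_max / t_min)^(i / (n_replicas - 1))
  temps[1] <- t_min
  temps[n_replicas] <- t_max
  temps
}
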