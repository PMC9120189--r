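#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; coordinates and radii in micrometers) into a validated
#' `morphology` data.frame. Type codes follow SWC semantics: 1 soma,
#' 2 axon, 3 dendrite.
#'
#' @param path SWC file.
#' @return A `morphology` data.frame with columns `id`, `type`, `x`, `y`,
#'   `z`, `radius`, `parent`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path)
  body <- grep("^\\s*[^#[:space:]]", lines)
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7L || anyNA(suppressWarnings(as.numeric(f)))) {
      stop("malformed SWC record at line ", i, ": '", lines[i], "'")
    }
    as.numeric(f)
  })
  m <- do.call(rbind, rows)
  morph <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  validate_morphology(morph)
}

validate_morphology <- function(morph) {
  if (anyDuplicated(morph$id)) stop("duplicate SWC node ids")
  if (any(morph$radius <= 0)) stop("all radii must be > 0")
  roots <- morph$id[morph$parent == -1L]
  if (length(roots) != 1L) {
    stop("morphology must have exactly one root (parent -1), found ",
         length(roots))
  }
  known <- c(-1L, morph$id)
  orphan <- setdiff(morph$parent, known)
  if (length(orphan) > 0) {
    stop("orphan parent id(s): ", paste(orphan, collapse = ", "))
  }
  # cycle check: walk each node to the root
  idx <- match(morph$parent, morph$id)
  for (i in seq_len(nrow(morph))) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("cycle detected at node id ", morph$id[i])
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  class(morph) <- c("morphology", "data.frame")
  morph
}

#' Write a morphology as SWC
#'
#' @param morph A `morphology`.
#' @param path Output file.
#' @export
write_swc <- function(morph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %g %g %g %g %d", morph$id, morph$type, morph$x,
                     morph$y, morph$z, morph$radius, morph$parent), con)
  invisible(path)
}

#' Generate a synthetic neuronal morphology
#'
#' Stand-in for reconstructed cortical cells: either a ball-and-stick cell
#' (spherical soma, straight axon along -y, `n_dend` straight dendrites
#' fanned in the upper hemisphere) or a branched cell whose dendritic
#' arbor is a full binary tree of the given depth. All three SWC type
#' codes (soma/axon/dendrite) are present. Reproducible per seed.
#'
#' @param template `"ball_and_stick"` or `"branched"`.
#' @param n_dend Number of dendrites (ball_and_stick); default 2.
#' @param depth Binary branching depth (branched); default 3.
#' @param axon_length Axon length (um); default 300.
#' @param dend_length Total dendrite length per branch path (um);
#'   default 150.
#' @param seg_length Compartment length (um); default 50.
#' @param soma_radius Soma radius (um); default 10.
#' @param seed RNG seed for branch-angle jitter.
#' @return A `morphology`.
#' @export
synth_morphology <- function(template = c("ball_and_stick", "branched"),
                             n_dend = 2L, depth = 3L, axon_length = 300,
                             dend_length = 150, seg_length = 50,
                             soma_radius = 10, seed = 1L) {
  template <- match.arg(template)
  stopifnot(axon_length > 0, dend_length > 0, seg_length > 0)
  set.seed(seed)
  rows <- list(c(1, 1, 0, 0, 0, soma_radius, -1))
  nid <- 1L
  add <- function(type, p0, dir, len, radius, parent) {
    n_seg <- max(1L, ceiling(len / seg_length))
    pts <- numeric(0)
    par <- parent
    for (s in seq_len(n_seg)) {
      nid <<- nid + 1L
      p <- p0 + dir * len * s / n_seg
      rows[[length(rows) + 1L]] <<- c(nid, type, p, radius, par)
      par <- nid
    }
    list(tip_id = par, tip = p0 + dir * len)
  }
  # axon straight down -y
  add(2L, c(0, 0, 0), c(0, -1, 0), axon_length, 1, 1L)
  if (template == "ball_and_stick") {
    stopifnot(n_dend >= 1L)
    for (k in seq_len(n_dend)) {
      phi <- 2 * pi * (k - 1) / n_dend + stats::runif(1, 0, 0.2)
      dir <- c(sin(phi) * 0.5, 0.8, cos(phi) * 0.5)
      dir <- dir / sqrt(sum(dir^2))
      add(3L, c(0, 0, 0), dir, dend_length, 1.5, 1L)
    }
  } else {
    # full binary arbor: 2 trunks from the soma, bifurcating at each of
    # `depth` levels -> 2^(depth+1) - 2 branch chains, 2^depth terminal tips
    stopifnot(depth >= 1L)
    grow <- function(p0, dir, level, parent) {
      res <- add(3L, p0, dir, dend_length / depth, 1.5, parent)
      if (level < depth) {
        for (sgn in c(-1, 1)) {
          ang <- sgn * (0.5 + stats::runif(1, 0, 0.15))
          rot <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0,
                          -sin(ang), 0, cos(ang)), 3, 3)
          grow(res$tip, as.numeric(rot %*% dir), level + 1L, res$tip_id)
        }
      }
    }
    for (sx in c(-1, 1)) {
      d0 <- c(sx * 0.4, 0.9, 0)
      grow(c(0, 0, 0), d0 / sqrt(sum(d0^2)), 1L, 1L)
    }
  }
  morph <- as.data.frame(do.call(rbind, rows))
  names(morph) <- c("id", "type", "x", "y", "z", "radius", "parent")
  morph$id <- as.integer(morph$id); morph$type <- as.integer(morph$type)
  morph$parent <- as.integer(morph$parent)
  validate_morphology(morph)
}

# Segment table: one row per (parent -> child) edge with endpoint
# coordinates; soma nodes are treated as point/sphere sources.
morph_segments <- function(morph) {
  idx <- match(morph$parent, morph$id)
  child <- which(!is.na(idx))
  data.frame(id = morph$id[child], type = morph$type[child],
             x0 = morph$x[idx[child]], y0 = morph$y[idx[child]],
             z0 = morph$z[idx[child]],
             x1 = morph$x[child], y1 = morph$y[child], z1 = morph$z[child],
             radius = morph$radius[child])
}

# Path distance (um) of each node from the root, along the tree.
node_path_dist <- function(morph) {
  idx <- match(morph$parent, morph$id)
  d <- rep(NA_real_, nrow(morph))
  d[is.na(idx)] <- 0
  # iterate until all filled (tree order not guaranteed in file)
  while (anyNA(d)) {
    todo <- which(is.na(d) & !is.na(d[idx]))
    if (length(todo) == 0L) stop("disconnected morphology")
    seglen <- sqrt((morph$x[todo] - morph$x[idx[todo]])^2 +
                   (morph$y[todo] - morph$y[idx[todo]])^2 +
                   (morph$z[todo] - morph$z[idx[todo]])^2)
    d[todo] <- d[idx[todo]] + seglen
  }
  d
}
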