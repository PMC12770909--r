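#' Cortical sheet: triangulated surface with normals, areas and region labels
#'
#' A `cortical_sheet` is the spatial support of every field in the package:
#' a triangulated surface (typically the grey-matter sheet), with per-node
#' outward unit normals, per-node areas (one third of each incident triangle,
#' so node areas sum to the total surface area), an integer region label per
#' node, and named *region sets* that group labels into the analysis regions
#' (the two stimulation targets `"M1_left"` / `"M1_right"` and the
#' `"surrounding"` grey matter).
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based node
#'   indices per row with consistent (counter-clockwise seen from outside)
#'   winding.
#' @param labels integer vector, one region label per node. Defaults to 0
#'   (unlabelled) everywhere.
#' @param region_sets named list mapping region-set names to integer label
#'   vectors. The three canonical names are `"M1_left"`, `"M1_right"` and
#'   `"surrounding"`; their label sets must be pairwise disjoint.
#'
#' @return An object of class `cortical_sheet`: a list with elements
#'   `nodes`, `triangles`, `normals`, `areas`, `labels`, `region_sets`.
#' @examples
#' tri <- matrix(c(1L, 2L, 3L), nrow = 1)
#' xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' sh <- cortical_sheet(xyz, tri)
#' sh$normals          # all (0, 0, 1): planar patch
#' sum(sh$areas)       # 0.5, the triangle area
#' @export
cortical_sheet <- function(nodes, triangles, labels = NULL,
                           region_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must have three columns (x, y, z)")
  if (ncol(triangles) != 3L) stop("`triangles` must have three columns")
  n <- nrow(nodes)
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("triangle indices must be in 1..", n)
  }
  if (!all(seq_len(n) %in% triangles)) {
    iso <- setdiff(seq_len(n), unique(as.vector(triangles)))
    stop("isolated node(s) not referenced by any triangle: ",
         paste(utils::head(iso, 5L), collapse = ", "))
  }
  if (is.null(labels)) labels <- integer(n)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("`labels` must have one entry per node")
  canon <- intersect(c("M1_left", "M1_right", "surrounding"),
                     names(region_sets))
  if (length(canon) > 1L) {
    pooled <- unlist(region_sets[canon], use.names = FALSE)
    if (anyDuplicated(pooled)) {
      stop("region sets M1_left / M1_right / surrounding must be disjoint")
    }
  }
  sheet <- structure(
    list(nodes = nodes, triangles = triangles,
         normals = NULL, areas = NULL,
         labels = labels, region_sets = region_sets),
    class = "cortical_sheet"
  )
  sheet$normals <- compute_vertex_normals(sheet)
  sheet$areas <- compute_vertex_areas(sheet)
  sheet
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat("<cortical_sheet> ", nrow(x$nodes), " nodes, ",
      nrow(x$triangles), " triangles, total area ",
      format(sum(x$areas), digits = 6), " mm^2\n", sep = "")
  if (length(x$region_sets)) {
    for (nm in names(x$region_sets)) {
      cat("  region set ", nm, ": ",
          sum(x$labels %in% x$region_sets[[nm]]), " nodes\n", sep = "")
    }
  }
  invisible(x)
}

# face normals (unnormalized: cross product, length = 2 * area) and areas
.face_geometry <- function(nodes, triangles) {
  a <- nodes[triangles[, 1L], , drop = FALSE]
  b <- nodes[triangles[, 2L], , drop = FALSE]
  c <- nodes[triangles[, 3L], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  area <- 0.5 * sqrt(rowSums(cr^2))
  list(cross = cr, area = area)
}

#' Angle-weighted outward vertex normals
#'
#' Each node's normal is the angle-weighted average of the unit normals of
#' its incident triangles (weight = interior angle at that node), normalized
#' to unit length. For closed surfaces the orientation is made outward:
#' if normals point towards the mesh centroid on balance, all are flipped.
#' Degenerate (zero-area) triangles contribute nothing and raise a warning.
#'
#' @param sheet a `cortical_sheet`, or any list with `nodes` and `triangles`.
#' @return numeric matrix, one unit 3-vector per node.
#' @export
compute_vertex_normals <- function(sheet) {
  nodes <- sheet$nodes
  triangles <- sheet$triangles
  fg <- .face_geometry(nodes, triangles)
  degen <- fg$area <= .Machine$double.eps * 100
  if (any(degen)) {
    warning(sum(degen), " degenerate (zero-area) triangle(s) ignored")
  }
  fn <- fg$cross / pmax(2 * fg$area, .Machine$double.xmin)
  fn[degen, ] <- 0
  acc <- matrix(0, nrow(nodes), 3L)
  for (k in 1:3) {
    i0 <- triangles[, k]
    i1 <- triangles[, if (k == 3L) 1L else k + 1L]
    i2 <- triangles[, if (k == 1L) 3L else k - 1L]
    e1 <- nodes[i1, , drop = FALSE] - nodes[i0, , drop = FALSE]
    e2 <- nodes[i2, , drop = FALSE] - nodes[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2) * rowSums(e2^2)), .Machine$double.xmin)
    ang <- acos(pmin(1, pmax(-1, cosang)))
    ang[degen] <- 0
    w <- fn * ang
    for (d in 1:3) {
      s <- rowsum(w[, d], i0, reorder = TRUE)
      idx <- as.integer(rownames(s))
      acc[idx, d] <- acc[idx, d] + s[, 1L]
    }
  }
  len <- sqrt(rowSums(acc^2))
  if (any(len <= 0)) stop("node with no valid incident triangle normal")
  nrm <- acc / len
  centroid <- colMeans(nodes)
  outward <- sum(nrm * sweep(nodes, 2L, centroid))
  if (outward < 0) nrm <- -nrm
  nrm
}

#' Per-node areas (one-third rule)
#'
#' Each node receives one third of the area of every incident triangle, so
#' node areas are non-negative and sum exactly to the total triangle area.
#'
#' @inheritParams compute_vertex_normals
#' @return numeric vector of areas in mm^2, one per node.
#' @export
compute_vertex_areas <- function(sheet) {
  nodes <- sheet$nodes
  triangles <- sheet$triangles
  fg <- .face_geometry(nodes, triangles)
  acc <- numeric(nrow(nodes))
  for (k in 1:3) {
    s <- rowsum(fg$area / 3, triangles[, k], reorder = TRUE)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1L]
  }
  acc
}

#' Signed cortex-normal component of a vector field
#'
#' Projects a per-node 3-vector field onto the outward unit normals:
#' positive values point out of the surface, negative values into it. The
#' normal component is the physiologically relevant direction for cortical
#' pyramidal-neurone polarization.
#'
#' @param field numeric matrix, one 3-vector per node (V/m).
#' @param normals numeric matrix of unit normals on the same node set.
#' @return numeric vector of signed components, one per node.
#' @export
normal_component <- function(field, normals) {
  field <- as.matrix(field)
  if (nrow(field) != nrow(normals)) {
    stop("`field` has ", nrow(field), " rows but `normals` has ",
         nrow(normals))
  }
  rowSums(field * normals)
}

#' Nodes belonging to a named region set
#'
#' @param sheet a `cortical_sheet`.
#' @param region_set a region-set name in `sheet$region_sets`, or a vector
#'   of names whose label sets are pooled.
#' @return integer vector of node indices.
#' @export
region_nodes <- function(sheet, region_set) {
  missing_sets <- setdiff(region_set, names(sheet$region_sets))
  if (length(missing_sets)) {
    stop("unknown region set(s): ", paste(missing_sets, collapse = ", "))
  }
  labs <- unique(unlist(sheet$region_sets[region_set], use.names = FALSE))
  which(sheet$labels %in% labs)
}
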