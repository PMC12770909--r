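# full-precision number formatting for exact text round-trips
.fmt <- function(x) sprintf("%.17g", x)

#' Read a surface mesh
#'
#' Supports Gmsh MSH v2 ASCII (as written by common forward-modelling
#' pipelines; triangle elements only, 1-based node ids) and ASCII PLY.
#' The format is chosen by file extension (`.msh` / `.ply`).
#'
#' @param path file path.
#' @return list with `nodes` (N x 3) and `triangles` (M x 3, 1-based),
#'   ready for [cortical_sheet()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = .read_msh(path),
         ply = .read_ply(path),
         stop("unsupported mesh format: .", ext, " (use .msh or .ply)"))
}

.read_msh <- function(path) {
  ln <- readLines(path)
  nstart <- match("$Nodes", ln)
  estart <- match("$Elements", ln)
  if (is.na(nstart) || is.na(estart)) stop("not a MSH v2 ASCII file: ", path)
  nn <- as.integer(ln[nstart + 1L])
  ntab <- matrix(scan(text = ln[(nstart + 2L):(nstart + 1L + nn)],
                      quiet = TRUE), nrow = nn, byrow = TRUE)
  # node ids need not be consecutive; remap to 1..N
  ids <- as.integer(ntab[, 1L])
  nodes <- ntab[, 2:4, drop = FALSE]
  ne <- as.integer(ln[estart + 1L])
  elems <- strsplit(ln[(estart + 2L):(estart + 1L + ne)], "[ \t]+")
  tri <- t(vapply(elems, function(e) {
    e <- as.integer(e)
    if (e[2L] != 2L) return(c(NA_integer_, NA_integer_, NA_integer_))
    ntags <- e[3L]
    e[(4L + ntags):(6L + ntags)]
  }, integer(3)))
  tri <- tri[!is.na(tri[, 1L]), , drop = FALSE]
  if (nrow(tri) == 0L) stop("no triangle elements in ", path)
  tri <- matrix(match(tri, ids), ncol = 3L)
  list(nodes = nodes, triangles = tri)
}

.read_ply <- function(path) {
  ln <- readLines(path)
  hend <- match("end_header", ln)
  if (is.na(hend) || ln[1L] != "ply") stop("not an ASCII PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", ln, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", ln, value = TRUE)))
  vtab <- matrix(scan(text = ln[(hend + 1L):(hend + nv)], quiet = TRUE),
                 nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  ftab <- t(vapply(strsplit(ln[(hend + nv + 1L):(hend + nv + nf)],
                            "[ \t]+"),
                   function(e) as.integer(e[2:4]) + 1L, integer(3)))
  list(nodes = vtab, triangles = ftab)
}

#' Write a surface mesh
#'
#' @param mesh list with `nodes` and `triangles` (or a `cortical_sheet`).
#' @param path output path ending in `.msh` (Gmsh v2 ASCII) or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  nodes <- mesh$nodes
  tri <- mesh$triangles
  if (ext == "msh") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
                 "$Nodes", as.character(nrow(nodes))), con)
    writeLines(paste(seq_len(nrow(nodes)), .fmt(nodes[, 1]),
                     .fmt(nodes[, 2]), .fmt(nodes[, 3])), con)
    writeLines(c("$EndNodes", "$Elements", as.character(nrow(tri))), con)
    writeLines(paste(seq_len(nrow(tri)), 2L, 2L, 0L, 0L,
                     tri[, 1], tri[, 2], tri[, 3]), con)
    writeLines("$EndElements", con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(nodes)),
                 "property float x", "property float y",
                 "property float z",
                 paste("element face", nrow(tri)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(paste(.fmt(nodes[, 1]), .fmt(nodes[, 2]),
                     .fmt(nodes[, 3])), con)
    writeLines(paste(3L, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  } else {
    stop("unsupported mesh format: .", ext)
  }
  invisible(path)
}

#' Read basis fields from a wide TSV container
#'
#' The container is a tab-separated table with a 0-based `node_index`
#' column and nine field columns `er1_x ... er2_z`, preceded by `#!`
#' metadata lines (`io`, `f`, `montage_id`, `individual_id`). Written by
#' [write_fields_tsv()] with full precision, so a write/read round trip
#' reproduces every array bit-for-bit.
#'
#' @param path file path.
#' @return a `basis_fields` object.
#' @export
read_fields_tsv <- function(path) {
  ln <- readLines(path)
  meta_ln <- grep("^#!", ln, value = TRUE)
  meta <- list()
  for (m in meta_ln) {
    kv <- strsplit(sub("^#!\\s*", "", m), "=", fixed = TRUE)[[1L]]
    meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  tab <- utils::read.table(text = ln[!startsWith(ln, "#")], header = TRUE,
                           sep = "\t", check.names = FALSE)
  tab <- tab[order(tab$node_index), , drop = FALSE]
  get3 <- function(stem) as.matrix(tab[paste0(stem, c("_x", "_y", "_z"))])
  basis_fields(get3("er1"), get3("ec1"), get3("er2"),
               io = as.numeric(meta$io %||% 2),
               f = as.numeric(meta$f %||% 20),
               montage_id = meta$montage_id %||% "montage",
               individual_id = meta$individual_id %||% "ind")
}

#' Write basis fields to a wide TSV container
#'
#' @param basis a `basis_fields` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fields_tsv <- function(basis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#! io=", .fmt(basis$io)),
               paste0("#! f=", .fmt(basis$f)),
               paste0("#! montage_id=", basis$montage_id),
               paste0("#! individual_id=", basis$individual_id)), con)
  hdr <- c("node_index",
           paste0(rep(c("er1", "ec1", "er2"), each = 3),
                  c("_x", "_y", "_z")))
  writeLines(paste(hdr, collapse = "\t"), con)
  body <- cbind(basis$er1, basis$ec1, basis$er2)
  lines <- apply(body, 1L, function(r) paste(.fmt(r), collapse = "\t"))
  writeLines(paste(seq_len(nrow(body)) - 1L, lines, sep = "\t"), con)
  invisible(path)
}

#' Read / write node region labels
#'
#' Two-column TSV with a 0-based `node_index` and an integer `label`.
#'
#' @param path file path.
#' @return integer label vector ordered by node.
#' @export
read_labels_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  tab <- tab[order(tab$node_index), , drop = FALSE]
  as.integer(tab$label)
}

#' @rdname read_labels_tsv
#' @param labels integer label vector.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(node_index = seq_along(labels) - 1L, label = labels),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
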