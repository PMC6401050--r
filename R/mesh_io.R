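#' Write a body model to disk
#'
#' Writes the mesh as a VTK legacy ASCII unstructured grid (tetra cells with
#' an integer cell-data material field) plus a JSON sidecar
#' (`<path>.meta.json`) holding the material code map, monitor points, body
#' dims, resolution and seed, so that [read_mesh()] round-trips losslessly.
#'
#' @param model A `body_model`.
#' @param path Output path for the `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(model, path) {
  stopifnot(inherits(model, "body_model"))
  if (nrow(model$elements) == 0L) stop("refusing to write an empty mesh")
  labels <- sort(unique(model$material))
  code <- match(model$material, labels) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "blastrat body model",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(model$nodes))), con)
  writeLines(apply(model$nodes, 1L, function(r)
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE), collapse = " ")), con)
  m <- nrow(model$elements)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(paste(4L, model$elements[, 1] - 1L, model$elements[, 2] - 1L,
                   model$elements[, 3] - 1L, model$elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS material int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(code), con)
  meta <- list(material_labels = as.list(stats::setNames(labels, as.character(seq_along(labels) - 1L))),
               body_dims = model$body_dims,
               resolution = model$resolution,
               seed = model$seed,
               monitor_points = model$monitor_points)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a body model from disk
#'
#' Parses a mesh written by [write_mesh()]. Exterior surface faces are
#' recomputed from the connectivity (they are a derived quantity), so the
#' round trip reproduces the original model exactly.
#'
#' @param path Path to the `.vtk` file (the `.meta.json` sidecar must sit
#'   next to it).
#' @return A `body_model`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("mesh sidecar not found: ", meta_path)
  lines <- readLines(path)
  expect_line <- function(i, pattern) {
    if (i > length(lines) || !grepl(pattern, lines[i]))
      stop("malformed VTK file at line ", i, ": expected '", pattern, "'")
  }
  expect_line(4L, "^DATASET UNSTRUCTURED_GRID")
  expect_line(5L, "^POINTS ")
  npts <- as.integer(strsplit(lines[5L], " ")[[1]][2])
  if (is.na(npts) || npts <= 0L) stop("malformed or empty mesh: bad POINTS count at line 5")
  pts <- matrix(scan(text = lines[6:(5 + npts)], quiet = TRUE), ncol = 3L, byrow = TRUE)
  i <- 6L + npts
  expect_line(i, "^CELLS ")
  ncell <- as.integer(strsplit(lines[i], " ")[[1]][2])
  if (is.na(ncell) || ncell <= 0L) stop("malformed or empty mesh: bad CELLS count at line ", i)
  cells <- matrix(scan(text = lines[(i + 1):(i + ncell)], quiet = TRUE),
                  ncol = 5L, byrow = TRUE)
  if (any(cells[, 1] != 4L)) stop("non-tetrahedral cell encountered at line ", i + which(cells[, 1] != 4L)[1])
  elems <- matrix(as.integer(cells[, 2:5] + 1L), ncol = 4L)
  i <- i + ncell + 1L
  expect_line(i, "^CELL_TYPES ")
  i <- i + ncell + 1L
  expect_line(i, "^CELL_DATA ")
  expect_line(i + 1L, "^SCALARS material")
  code <- as.integer(scan(text = lines[(i + 3):(i + 2 + ncell)], quiet = TRUE))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  labmap <- meta$material_labels
  unknown <- setdiff(as.character(unique(code)), names(labmap))
  if (length(unknown) > 0L)
    stop("unknown material code(s) in mesh: ", paste(unknown, collapse = ", "))
  material <- unlist(labmap)[as.character(code)]
  names(material) <- NULL
  known <- c("lung_L", "lung_R", "heart", "rib", "skin_muscle")
  bad <- setdiff(unique(material), known)
  if (length(bad) > 0L)
    stop("unknown material label(s): ", paste(bad, collapse = ", "))
  mp <- meta$monitor_points
  if (!is.null(mp) && length(mp) > 0L) mp <- as.data.frame(mp) else mp <- NULL
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(list(nodes = pts,
                 elements = elems,
                 material = material,
                 surface_faces = boundary_faces(pts, elems)$faces,
                 monitor_points = mp,
                 body_dims = as.numeric(meta$body_dims),
                 resolution = as.numeric(meta$resolution),
                 seed = as.integer(meta$seed)),
            class = "body_model")
}
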