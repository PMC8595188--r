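# Readers and writers: surface meshes (ASCII PLY/OFF/STL), YAML run
# configuration, VTK field exports, TSV tables and the run manifest.
# All coordinates are nm by declaration in the file headers.

#' Write a membrane mesh
#'
#' ASCII PLY, OFF or STL, chosen by file extension. Reference coordinates
#' are written; PLY carries a comment declaring nm units.
#'
#' @param mesh membrane mesh
#' @param path output path (.ply, .off or .stl)
#' @export
write_mesh <- function(mesh, path) {
  V <- mesh$Vref
  tri <- mesh$tri
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.9g", x)
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0", "comment units nm",
                 paste("element vertex", nrow(V)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(tri)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(paste(fmt(V[, 1]), fmt(V[, 2]), fmt(V[, 3])), con)
    writeLines(paste(3, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  } else if (ext == "off") {
    writeLines(c("OFF", paste(nrow(V), nrow(tri), 0L)), con)
    writeLines(paste(fmt(V[, 1]), fmt(V[, 2]), fmt(V[, 3])), con)
    writeLines(paste(3, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  } else if (ext == "stl") {
    writeLines("solid membrane", con)
    for (t in seq_len(nrow(tri))) {
      a <- V[tri[t, 1], ]; b <- V[tri[t, 2], ]; cc <- V[tri[t, 3], ]
      nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
               (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
               (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
      nl <- sqrt(sum(nrm^2))
      if (nl > 0) nrm <- nrm / nl
      writeLines(c(paste("facet normal", paste(fmt(nrm), collapse = " ")),
                   "  outer loop",
                   paste("    vertex", paste(fmt(a), collapse = " ")),
                   paste("    vertex", paste(fmt(b), collapse = " ")),
                   paste("    vertex", paste(fmt(cc), collapse = " ")),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid membrane", con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' Read a surface mesh
#'
#' ASCII PLY, OFF or STL. STL files (which carry no connectivity) are
#' welded: vertices closer than `weld_tol` are merged. Degenerate
#' triangles are rejected with the offending element list.
#'
#' @param path input path
#' @param weld_tol vertex welding tolerance for STL (nm)
#' @return a `canaflow_mesh` (open, non-periodic; reference = current)
#' @export
read_mesh <- function(path, weld_tol = 1e-3) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty mesh file: ", path)
  if (ext == "ply") {
    if (!identical(lines[1], "ply")) stop("not a PLY file: ", path)
    hend <- match("end_header", lines)
    if (is.na(hend)) stop("malformed PLY header (no end_header)")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex ", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face ", lines, value = TRUE)[1]))
    if (is.na(nv) || is.na(nf)) stop("malformed PLY header")
    vl <- lines[(hend + 1):(hend + nv)]
    V <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                ncol = 3, byrow = TRUE)
    fl <- lines[(hend + nv + 1):(hend + nv + nf)]
    fv <- lapply(strsplit(trimws(fl), "\\s+"), as.integer)
    if (any(vapply(fv, `[`, integer(1), 1) != 3L))
      stop("non-triangular faces in PLY")
    tri <- do.call(rbind, lapply(fv, function(x) x[2:4] + 1L))
  } else if (ext == "off") {
    if (!identical(trimws(lines[1]), "OFF")) stop("not an OFF file: ", path)
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    V <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"))),
                ncol = 3, byrow = TRUE)
    fv <- lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"),
                 as.integer)
    tri <- do.call(rbind, lapply(fv, function(x) x[2:4] + 1L))
  } else if (ext == "stl") {
    if (!grepl("^solid", lines[1])) stop("not an ASCII STL file: ", path)
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("malformed STL: vertex count not a multiple of 3")
    raw <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                           function(x) x[2:4]))),
                  ncol = 3, byrow = TRUE)
    key <- apply(round(raw / weld_tol), 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    first <- !duplicated(key)
    V <- raw[first, , drop = FALSE]
    tri <- matrix(uid, ncol = 3, byrow = TRUE)
  } else stop("unsupported mesh format: .", ext)
  a <- V[tri[, 1], , drop = FALSE]
  d1 <- V[tri[, 2], , drop = FALSE] - a
  d2 <- V[tri[, 3], , drop = FALSE] - a
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (any(area <= 1e-6))
    stop("degenerate triangles on read: ",
         paste(head(which(area <= 1e-6), 10), collapse = ", "))
  mesh <- structure(list(V = V, Vref = V, tri = tri, Lz = NA_real_,
                         closed = FALSE, n_phi = NA_integer_,
                         n_rows = NA_integer_),
                    class = "canaflow_mesh")
  mesh_precompute(mesh)
}

#' Read a run configuration file
#'
#' Plain declarative YAML with the sections of [sim_config()]; missing
#' fields are filled with the canalicular defaults, unknown keys rejected.
#'
#' @param path YAML file
#' @return a validated `canaflow_config`
#' @export
read_config <- function(path) {
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  do.call(sim_config, ov)
}

#' Write a configuration file
#' @param cfg a `canaflow_config`
#' @param path output YAML path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# legacy-VTK structured-points export of the voxel fields
write_vtk_grid <- function(lat, u, p, path) {
  d <- lat$domain
  dims <- d$dims
  n <- prod(dims)
  lab <- as.integer(d$labels)
  full <- function(v) {
    out <- numeric(n)
    out[lat$fluid] <- v
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "canaflow steady fields (units nm, nm/s, Pa)", "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       d$origin[1] + d$dx / 2, d$origin[2] + d$dx / 2,
                       d$origin[3] + d$dx / 2),
               sprintf("SPACING %.9g %.9g %.9g", d$dx, d$dx, d$dx),
               paste("POINT_DATA", n),
               "SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(lab), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", full(p)), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     full(u[, 1]), full(u[, 2]), full(u[, 3])), con)
  invisible(path)
}

# legacy-VTK unstructured-grid export of the membrane with cell strain
write_vtk_membrane <- function(mesh, strain, path) {
  V <- mesh$V
  tri <- mesh$tri
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "canaflow membrane (units nm)", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(V), "double")), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(paste("CELLS", nrow(tri), 4L * nrow(tri)), con)
  writeLines(paste(3, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  writeLines(paste("CELL_TYPES", nrow(tri)), con)
  writeLines(rep("5", nrow(tri)), con)
  writeLines(c(paste("CELL_DATA", nrow(tri)),
               "SCALARS max_principal_strain double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.12g", strain), con)
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a result bundle to a run directory
#'
#' Writes the steady voxel fields (VTK structured points), the deformed
#' membrane with per-element strain (VTK unstructured grid + TSV), the TE
#' table, the summary statistics, and a JSON manifest with the config
#' snapshot, seeds and file digests. File naming is deterministic;
#' re-export yields byte-identical tables.
#'
#' @param bundle a `canaflow_result`
#' @param dir output directory (created if missing)
#' @param lat optional lattice for the voxel-field export (geometry of the
#'   run); voxel fields are skipped when absent
#' @return invisibly, the manifest path
#' @export
export_fields <- function(bundle, dir, lat = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("seed%d_%s", bundle$te_seed,
                 if (bundle$direction > 0) "posz" else "negz")
  files <- character(0)
  f <- file.path(dir, paste0("membrane_", tag, ".vtk"))
  write_vtk_membrane(bundle$mesh, bundle$strain, f)
  files <- c(files, f)
  if (!is.null(lat)) {
    f <- file.path(dir, paste0("fields_", tag, ".vtk"))
    write_vtk_grid(lat, bundle$u, bundle$p, f)
    files <- c(files, f)
  }
  ctr <- mesh_centroids(bundle$mesh)
  f <- file.path(dir, paste0("strain_", tag, ".tsv"))
  write_tsv(data.frame(element = seq_along(bundle$strain),
                       cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                       max_principal_strain = bundle$strain), f)
  files <- c(files, f)
  te <- bundle$tethers
  f <- file.path(dir, paste0("tethers_", tag, ".tsv"))
  xm <- bundle$mesh$Vref[te$attachment, , drop = FALSE]
  write_tsv(data.frame(id = seq_along(te$attachment),
                       vertex = te$attachment,
                       xm_x = xm[, 1], xm_y = xm[, 2], xm_z = xm[, 3],
                       xw_x = te$x_w[, 1], xw_y = te$x_w[, 2],
                       xw_z = te$x_w[, 3],
                       l0 = te$l0, k_sp = te$k_sp, theta = te$theta,
                       tension = bundle$tension), f)
  files <- c(files, f)
  manifest <- list(
    package = "canaflow",
    version = as.character(utils::packageVersion("canaflow")),
    config = unclass(bundle$config),
    te_seed = bundle$te_seed,
    direction = bundle$direction,
    geometry = bundle$geometry_metadata,
    steps = bundle$steps,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  mf <- file.path(dir, paste0("manifest_", tag, ".json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mf)
}
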