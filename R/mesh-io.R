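#' Read a triangle mesh from a standard ASCII format
#'
#' Supports OFF, OBJ, STL (ASCII), PLY (ASCII) and legacy VTK POLYDATA.
#' The format is inferred from the file extension unless given explicitly.
#' Non-watertight inputs load successfully; the condition is flagged in the
#' returned mesh diagnostics (`$watertight`).
#'
#' @param path file path
#' @param format one of `"off"`, `"obj"`, `"stl"`, `"ply"`, `"vtk"`; default
#'   inferred from the extension
#' @return a [surface_mesh()].
#' @export
load_surface_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  fmt <- match.arg(format, c("off", "obj", "stl", "ply", "vtk"))
  lines <- readLines(path, warn = FALSE)
  switch(fmt,
         off = read_off(lines, path),
         obj = read_obj(lines, path),
         stl = read_stl(lines, path),
         ply = read_ply(lines, path),
         vtk = read_vtk(lines, path))
}

#' Write a triangle mesh to a standard ASCII format
#'
#' @param mesh a [surface_mesh()]
#' @param path output file path
#' @param format format name; default inferred from the extension
#' @return `path`, invisibly.
#' @rdname load_surface_mesh
#' @export
save_surface_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  fmt <- match.arg(format, c("off", "obj", "stl", "ply", "vtk"))
  v <- mesh$vertices; f <- mesh$faces
  vfmt <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                                    collapse = " "))
  txt <- switch(fmt,
    off = c("OFF", paste(nrow(v), nrow(f), 0L), vfmt(v),
            apply(f, 1, function(r) paste(c(3L, r - 1L), collapse = " "))),
    obj = c(paste("v", vfmt(v)),
            apply(f, 1, function(r) paste(c("f", r), collapse = " "))),
    stl = c("solid mesh",
            unlist(lapply(seq_len(nrow(f)), function(i) c(
              paste("facet normal",
                    paste(sprintf("%.17g", mesh$face_normals[i, ]),
                          collapse = " ")),
              "  outer loop",
              paste("    vertex", vfmt(v[f[i, ], , drop = FALSE])),
              "  endloop", "endfacet"))),
            "endsolid mesh"),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(v)),
            "property double x", "property double y", "property double z",
            paste("element face", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            vfmt(v),
            apply(f, 1, function(r) paste(c(3L, r - 1L), collapse = " "))),
    vtk = c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
            "DATASET POLYDATA", paste("POINTS", nrow(v), "double"), vfmt(v),
            paste("POLYGONS", nrow(f), 4L * nrow(f)),
            apply(f, 1, function(r) paste(c(3L, r - 1L), collapse = " "))))
  writeLines(txt, path)
  invisible(path)
}

parse_nums <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])

# vapply leaves the source lines as dimnames; strip them so loaded meshes
# compare cleanly with generated ones
bare <- function(m) { dimnames(m) <- NULL; m }

read_off <- function(lines, path) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF")
    stop("malformed OFF file (missing OFF header): ", path)
  hd <- parse_nums(lines[2])
  if (length(hd) < 2 || any(is.na(hd[1:2])))
    stop("malformed OFF count record (line 2): ", path)
  nv <- hd[1]; nf <- hd[2]
  v <- t(vapply(lines[3:(2 + nv)], function(s) parse_nums(s)[1:3],
                numeric(3)))
  f <- t(vapply(lines[(3 + nv):(2 + nv + nf)], function(s) {
    x <- parse_nums(s)
    if (x[1] != 3) stop("non-triangular face in OFF file: ", path)
    x[2:4] + 1
  }, numeric(3)))
  surface_mesh(bare(v), bare(f), check = FALSE)
}

read_obj <- function(lines, path) {
  vlin <- grep("^v\\s", lines, value = TRUE)
  flin <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlin) || !length(flin))
    stop("malformed OBJ file (no v/f records): ", path)
  v <- t(vapply(vlin, function(s) parse_nums(sub("^v", "", s))[1:3],
                numeric(3)))
  f <- t(vapply(flin, function(s) {
    toks <- strsplit(trimws(sub("^f", "", s)), "[[:space:]]+")[[1]]
    if (length(toks) != 3) stop("non-triangular face in OBJ file: ", path)
    as.numeric(vapply(strsplit(toks, "/"), `[`, "", 1))
  }, numeric(3)))
  surface_mesh(bare(v), bare(f), check = FALSE)
}

read_stl <- function(lines, path) {
  vlin <- grep("^\\s*vertex\\s", lines)
  if (length(vlin) == 0 || length(vlin) %% 3 != 0)
    stop("malformed ASCII STL (vertex record count): ", path)
  vv <- t(vapply(lines[vlin],
                 function(s) parse_nums(sub("^\\s*vertex", "", s))[1:3],
                 numeric(3)))
  # deduplicate shared vertices so connectivity is recovered
  key <- apply(vv, 1, function(r) paste(sprintf("%.12g", r), collapse = ","))
  uk <- unique(key)
  idx <- match(key, uk)
  v <- vv[!duplicated(key), , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(bare(v), bare(f), check = FALSE)
}

read_ply <- function(lines, path) {
  hend <- which(trimws(lines) == "end_header")[1]
  if (is.na(hend)) stop("malformed PLY (no end_header): ", path)
  hdr <- lines[1:hend]
  if (any(grepl("format\\s+binary", hdr)))
    stop("binary PLY not supported: ", path)
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY element counts: ", path)
  v <- t(vapply(lines[hend + 1:nv], function(s) parse_nums(s)[1:3],
                numeric(3)))
  f <- t(vapply(lines[hend + nv + 1:nf], function(s) {
    x <- parse_nums(s)
    if (x[1] != 3) stop("non-triangular face in PLY file: ", path)
    x[2:4] + 1
  }, numeric(3)))
  surface_mesh(bare(v), bare(f), check = FALSE)
}

read_vtk <- function(lines, path) {
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("malformed VTK (no POINTS record): ", path)
  np <- as.integer(strsplit(trimws(lines[ip]), "[[:space:]]+")[[1]][2])
  nums <- numeric(0); i <- ip + 1
  while (length(nums) < 3 * np) {
    nums <- c(nums, parse_nums(lines[i])); i <- i + 1
  }
  v <- matrix(nums[1:(3 * np)], ncol = 3, byrow = TRUE)
  ifc <- grep("^POLYGONS", lines)[1]
  if (is.na(ifc)) stop("malformed VTK (no POLYGONS record): ", path)
  nfc <- as.integer(strsplit(trimws(lines[ifc]), "[[:space:]]+")[[1]][2])
  f <- t(vapply(lines[ifc + 1:nfc], function(s) {
    x <- parse_nums(s)
    if (x[1] != 3) stop("non-triangular polygon in VTK file: ", path)
    x[2:4] + 1
  }, numeric(3)))
  surface_mesh(bare(v), bare(f), check = FALSE)
}
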