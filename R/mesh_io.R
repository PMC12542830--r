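# Mesh and activation-map I/O.
#
# openCARP text formats: .pts (count header, "x y z" per line), .elem
# (count header, "Tt n1 n2 n3 n4 tag" with 0-based node ids), .lon (header
# "1", one fibre vector per element).  VTK unstructured grid (.vtu, ASCII
# XML) carries point data "activation_ms", "uvc_rho", "uvc_tau", "uvc_phi"
# and cell data "region" (integer codes into REGION_LEVELS) and "fibre".

#' Write a mesh to disk
#'
#' @param mesh a `tet_mesh`.
#' @param path output path: for `format = "carp"` the base name (writes
#'   `<path>.pts/.elem/.lon`), for `format = "vtu"` the file name.
#' @param format "carp" or "vtu".
#' @param uvc optional `uvc` (stored as point data in vtu output).
#' @param activation optional [activation_map()] (vtu point data).
#' @return the path invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("carp", "vtu"), uvc = NULL,
                       activation = NULL) {
  format <- match.arg(format)
  if (format == "carp") .write_carp(mesh, path) else
    .write_vtu(mesh, path, uvc = uvc, activation = activation)
  invisible(path)
}

#' Read a mesh from disk
#'
#' @param path base name (carp) or file name (vtu).
#' @param format "carp" or "vtu".
#' @param require_fibres error if no fibre information is present
#'   (missing `.lon` file for carp input).
#' @return list(mesh, uvc) where uvc is NULL unless the file carries UVC
#'   point data.
#' @export
read_mesh <- function(path, format = c("carp", "vtu"),
                      require_fibres = FALSE) {
  format <- match.arg(format)
  if (format == "carp") .read_carp(path, require_fibres) else
    .read_vtu(path, require_fibres)
}

.num <- function(x) sprintf("%.10g", x)

.write_carp <- function(mesh, base) {
  pts <- file.path(paste0(base, ".pts"))
  writeLines(c(as.character(nrow(mesh$nodes)),
               paste(.num(mesh$nodes[, 1]), .num(mesh$nodes[, 2]),
                     .num(mesh$nodes[, 3]))), pts)
  reg <- match(mesh$region, REGION_LEVELS) - 1L
  writeLines(c(as.character(nrow(mesh$tets)),
               paste("Tt", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L, reg)),
             paste0(base, ".elem"))
  if (!is.null(mesh$fibre))
    writeLines(c("1", paste(.num(mesh$fibre[, 1]), .num(mesh$fibre[, 2]),
                            .num(mesh$fibre[, 3]))),
               paste0(base, ".lon"))
  invisible(base)
}

.parse_fail <- function(file, line, why) {
  stop("parse error in ", file, " at line ", line, ": ", why, call. = FALSE)
}

.read_carp <- function(base, require_fibres) {
  ptsf <- paste0(base, ".pts"); elemf <- paste0(base, ".elem")
  lonf <- paste0(base, ".lon")
  if (!file.exists(ptsf)) stop("missing points file: ", ptsf)
  if (!file.exists(elemf)) stop("missing elements file: ", elemf)
  ln <- readLines(ptsf)
  n <- suppressWarnings(as.integer(ln[1]))
  if (is.na(n)) .parse_fail(ptsf, 1, "node count expected")
  if (length(ln) < n + 1) .parse_fail(ptsf, length(ln), "file truncated")
  sp <- strsplit(trimws(ln[1 + seq_len(n)]), "[ \t]+")
  if (any(lengths(sp) != 3))
    .parse_fail(ptsf, 1 + which(lengths(sp) != 3)[1], "expected x y z")
  nodes <- matrix(as.numeric(unlist(sp)), ncol = 3, byrow = TRUE)
  if (anyNA(nodes)) .parse_fail(ptsf, 0, "non-numeric coordinate")
  ln <- readLines(elemf)
  m <- suppressWarnings(as.integer(ln[1]))
  if (is.na(m)) .parse_fail(elemf, 1, "element count expected")
  if (length(ln) < m + 1) .parse_fail(elemf, length(ln), "file truncated")
  sp <- strsplit(trimws(ln[1 + seq_len(m)]), "[ \t]+")
  bad <- which(vapply(sp, function(s) s[1] != "Tt" || length(s) < 5,
                      logical(1)))
  if (length(bad))
    .parse_fail(elemf, 1 + bad[1], "expected 'Tt n1 n2 n3 n4 [tag]'")
  tets <- t(vapply(sp, function(s) as.integer(s[2:5]), integer(4))) + 1L
  if (anyNA(tets) || any(tets < 1) || any(tets > n))
    .parse_fail(elemf, 0, "node index out of range")
  tag <- vapply(sp, function(s) if (length(s) >= 6) as.integer(s[6]) else 0L,
                integer(1))
  region <- REGION_LEVELS[tag + 1L]
  region[is.na(region)] <- "LV_MYO"
  fibre <- NULL
  if (file.exists(lonf)) {
    ln <- readLines(lonf)
    sp <- strsplit(trimws(ln[-1]), "[ \t]+")
    sp <- sp[lengths(sp) > 0]
    if (length(sp) != m) .parse_fail(lonf, length(ln), paste0(
      "expected ", m, " fibre vectors, found ", length(sp)))
    fibre <- matrix(as.numeric(unlist(lapply(sp, `[`, 1:3))), ncol = 3,
                    byrow = TRUE)
    nn <- sqrt(rowSums(fibre^2))
    fibre <- fibre / ifelse(nn > 0, nn, 1)
  } else if (require_fibres) {
    stop("fibre file required but not found: ", lonf)
  }
  chamber <- ifelse(region == "RV_MYO", "RV", "LV")
  list(mesh = tet_mesh(nodes, tets, region, chamber, fibre), uvc = NULL)
}

.da <- function(name, values, ncomp = 1, type = "Float64") {
  c(sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
            type, name, ncomp),
    paste(values, collapse = " "), "</DataArray>")
}

.write_vtu <- function(mesh, path, uvc = NULL, activation = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  pd <- character(0)
  if (!is.null(activation)) {
    tt <- activation$node_time
    tt[!is.finite(tt)] <- -1
    pd <- c(pd, .da("activation_ms", .num(tt)))
  }
  if (!is.null(uvc))
    pd <- c(pd, .da("uvc_rho", .num(uvc$rho)), .da("uvc_tau", .num(uvc$tau)),
            .da("uvc_phi", .num(uvc$phi)),
            .da("uvc_ventricle", as.integer(uvc$ventricle == "RV"),
                type = "Int32"))
  cd <- .da("region", match(mesh$region, REGION_LEVELS) - 1L, type = "Int32")
  if (!is.null(mesh$fibre))
    cd <- c(cd, .da("fibre", paste(.num(mesh$fibre[, 1]),
                                   .num(mesh$fibre[, 2]),
                                   .num(mesh$fibre[, 3])), ncomp = 3))
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    "<Points>",
    .da("Points", paste(.num(mesh$nodes[, 1]), .num(mesh$nodes[, 2]),
                        .num(mesh$nodes[, 3])), ncomp = 3),
    "</Points>",
    "<Cells>",
    .da("connectivity", paste(mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                              mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L),
        type = "Int64"),
    .da("offsets", paste(seq_len(m) * 4L, collapse = " "), type = "Int64"),
    .da("types", paste(rep(10L, m), collapse = " "), type = "UInt8"),
    "</Cells>",
    if (length(pd)) c("<PointData>", pd, "</PointData>"),
    "<CellData>", cd, "</CellData>",
    "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(xml, path)
  invisible(path)
}

.read_vtu <- function(path, require_fibres = FALSE) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("no <Piece> in ", path)
  arr <- function(xp) {
    nd <- xml2::xml_find_first(doc, xp)
    if (inherits(nd, "xml_missing")) return(NULL)
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "[ \t\r\n]+")[[1]])
  }
  pts <- arr(".//Points/DataArray")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- arr(".//Cells/DataArray[@Name='connectivity']")
  tets <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  reg <- arr(".//CellData/DataArray[@Name='region']")
  region <- if (is.null(reg)) rep("LV_MYO", nrow(tets))
            else REGION_LEVELS[as.integer(reg) + 1L]
  fib <- arr(".//CellData/DataArray[@Name='fibre']")
  fibre <- if (is.null(fib)) NULL else matrix(fib, ncol = 3, byrow = TRUE)
  if (require_fibres && is.null(fibre))
    stop("fibre data required but absent from ", path)
  chamber <- ifelse(region == "RV_MYO", "RV", "LV")
  mesh <- tet_mesh(nodes, tets, region, chamber, fibre)
  rho <- arr(".//PointData/DataArray[@Name='uvc_rho']")
  uvc <- NULL
  if (!is.null(rho)) {
    vent <- arr(".//PointData/DataArray[@Name='uvc_ventricle']")
    uvc <- uvc_coords(rho, arr(".//PointData/DataArray[@Name='uvc_tau']"),
                      arr(".//PointData/DataArray[@Name='uvc_phi']"),
                      ifelse(!is.null(vent) & vent == 1, "RV", "LV"))
  }
  act <- arr(".//PointData/DataArray[@Name='activation_ms']")
  if (!is.null(act)) {
    act[act < 0] <- Inf
    attr(mesh, "activation") <- act
  }
  list(mesh = mesh, uvc = uvc)
}

#' Write an activation map as CSV
#'
#' Columns node_id (1-based) and time_ms; unreached nodes are written as
#' empty fields.
#' @param act an [activation_map()].
#' @param path output file.
#' @return the path invisibly.
#' @export
write_activation_csv <- function(act, path) {
  tt <- act$node_time
  df <- data.frame(node_id = seq_along(tt),
                   time_ms = ifelse(is.finite(tt), tt, NA_real_))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a Purkinje tree as legacy-VTK polylines
#'
#' @param tree a `purkinje_tree`.
#' @param path output .vtk file.
#' @return the path invisibly.
#' @export
write_tree_vtk <- function(tree, path) {
  ne <- nrow(tree$edges)
  xml <- c("# vtk DataFile Version 3.0", "purkinje tree", "ASCII",
           "DATASET POLYDATA",
           sprintf("POINTS %d double", nrow(tree$nodes)),
           paste(.num(tree$nodes[, 1]), .num(tree$nodes[, 2]),
                 .num(tree$nodes[, 3])),
           sprintf("LINES %d %d", ne, 3L * ne),
           paste(2L, tree$edges$a - 1L, tree$edges$b - 1L),
           sprintf("CELL_DATA %d", ne),
           "SCALARS blocked int 1", "LOOKUP_TABLE default",
           paste(as.integer(tree$edges$blocked)))
  writeLines(xml, path)
  invisible(path)
}
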