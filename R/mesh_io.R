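# Mesh readers and writers: Gmsh MSH v4.1 (ASCII) and VTK VTU (XML ASCII).
#
# Both dialects carry the element region as integer cell data (MSH: one
# element block per region with the region code as entity tag, plus a
# $ElementData field "region"; VTU: a CellData array "region") and the node
# sets as 0/1 integer point-data masks named "nodeset_<NAME>".  Coordinates
# are printed with 17 significant digits so a write/read round trip is
# bit-exact.  Contact pairs and pretension sections are run-time constructs
# of the generator and are not part of either dialect; a re-read DCP mesh
# therefore contains the duplicated interface nodes but no active contact
# definition.

fmt_g <- function(x) sprintf("%.17g", x)

#' Write a mesh to disk
#'
#' @param mesh An `fh_mesh`.
#' @param path Output path ending in `.msh` (Gmsh MSH v4.1 ASCII) or `.vtu`
#'   (VTK XML unstructured grid, ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "fh_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    msh = write_msh4(mesh, path),
    vtu = write_vtu(mesh, path),
    stop(sprintf("unsupported mesh format '.%s' (supported dialects: Gmsh MSH v4 '.msh', VTK VTU '.vtu')", ext))
  )
  invisible(path)
}

#' Read a mesh from disk
#'
#' Reads a tetrahedral mesh with region tags and node-set masks from a file
#' written by [write_mesh()] (or a compatible exporter).  A file without a
#' `region` integer cell-data field is rejected.
#'
#' @param path Path ending in `.msh` or `.vtu`.
#' @return An `fh_mesh` (without contact pairs or pretension sections).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    msh = read_msh4(path),
    vtu = read_vtu(path),
    stop(sprintf("unsupported mesh format '.%s' (supported dialects: Gmsh MSH v4 '.msh', VTK VTU '.vtu')", ext))
  )
}

write_msh4 <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$tets)
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$Nodes")
  w(sprintf("1 %d 1 %d", n, n))
  w(sprintf("3 1 0 %d", n))
  w(sprintf("%d", seq_len(n)))
  w(paste(fmt_g(mesh$nodes[, 1]), fmt_g(mesh$nodes[, 2]), fmt_g(mesh$nodes[, 3])))
  w("$EndNodes")
  regions <- sort(unique(mesh$region))
  w("$Elements")
  w(sprintf("%d %d 1 %d", length(regions), e, e))
  tag0 <- 0L
  for (rg in regions) {
    idx <- which(mesh$region == rg)
    w(sprintf("3 %d 4 %d", rg, length(idx)))
    tt <- mesh$tets[idx, , drop = FALSE]
    w(paste(tag0 + seq_along(idx), tt[, 1], tt[, 2], tt[, 3], tt[, 4]))
    tag0 <- tag0 + length(idx)
  }
  w("$EndElements")
  for (nm in names(mesh$node_sets)) {
    set <- mesh$node_sets[[nm]]
    w("$NodeData", "1", sprintf("\"nodeset_%s\"", nm), "1", "0", "3", "0", "1",
      sprintf("%d", length(set)))
    if (length(set)) w(paste(set, "1"))
    w("$EndNodeData")
  }
  invisible(path)
}

read_msh4 <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name))
    i1 <- which(lines == paste0("$End", name))
    if (length(i0) != 1L || length(i1) != 1L) {
      stop(sprintf("MSH file lacks a $%s section", name))
    }
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(sec("MeshFormat")[1], "\\s+")[[1]]
  if (!startsWith(fmt[1], "4")) {
    stop("only the Gmsh MSH v4 ASCII dialect is supported, file declares version ", fmt[1])
  }
  nd <- sec("Nodes")
  hdr <- as.numeric(strsplit(nd[1], "\\s+")[[1]])
  n_blocks <- hdr[1]; n_nodes <- hdr[2]
  coords <- matrix(NA_real_, n_nodes, 3)
  pos <- 2L
  for (b in seq_len(n_blocks)) {
    bh <- as.numeric(strsplit(nd[pos], "\\s+")[[1]])
    nb <- bh[4]
    tags <- as.integer(nd[pos + seq_len(nb)])
    xyz <- do.call(rbind, lapply(nd[pos + nb + seq_len(nb)], function(s) {
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    }))
    coords[tags, ] <- xyz[, 1:3]
    pos <- pos + 2L * nb + 1L
  }
  el <- sec("Elements")
  ehdr <- as.numeric(strsplit(el[1], "\\s+")[[1]])
  e_blocks <- ehdr[1]
  tets <- NULL; region <- integer()
  pos <- 2L
  for (b in seq_len(e_blocks)) {
    bh <- as.numeric(strsplit(el[pos], "\\s+")[[1]])
    etype <- bh[3]; nb <- bh[4]
    rows <- do.call(rbind, lapply(el[pos + seq_len(nb)], function(s) {
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    }))
    if (etype == 4) {
      tets <- rbind(tets, rows[, 2:5, drop = FALSE])
      region <- c(region, rep(as.integer(bh[2]), nb))
    }
    pos <- pos + nb + 1L
  }
  if (is.null(tets)) stop("MSH file contains no tetrahedral elements")
  if (any(region < 1L) || any(region > length(REGION_LEVELS))) {
    stop("MSH element entity tags must encode the region codes 1..5 (cell-data name 'region')")
  }
  node_sets <- list()
  starts <- which(lines == "$NodeData")
  for (i0 in starts) {
    i1 <- which(lines == "$EndNodeData")
    i1 <- min(i1[i1 > i0])
    block <- lines[(i0 + 1L):(i1 - 1L)]
    # layout: n_str, strings..., n_real, reals..., n_int, ints..., entries
    p <- 1L
    n_str <- as.integer(block[p])
    nm <- gsub("\"", "", block[p + 1L])
    p <- p + n_str + 1L
    n_real <- as.integer(block[p]); p <- p + n_real + 1L
    n_int <- as.integer(block[p]); ints <- as.integer(block[p + seq_len(n_int)])
    p <- p + n_int + 1L
    n_entries <- ints[n_int]
    ids <- integer()
    if (n_entries > 0) {
      rows <- do.call(rbind, lapply(block[p + seq_len(n_entries) - 1L], function(s) {
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])
      }))
      ids <- as.integer(rows[rows[, 2] != 0, 1])
    }
    if (startsWith(nm, "nodeset_")) {
      node_sets[[sub("^nodeset_", "", nm)]] <- sort(ids)
    }
  }
  new_fh_mesh(coords, matrix(as.integer(tets), ncol = 4), region, node_sets)
}

write_vtu <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$tets)
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    ' <UnstructuredGrid>',
    sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, e),
    '   <Points>',
    '    <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(paste(fmt_g(mesh$nodes[, 1]), fmt_g(mesh$nodes[, 2]), fmt_g(mesh$nodes[, 3])))
  w('    </DataArray>', '   </Points>', '   <Cells>',
    '    <DataArray type="Int64" Name="connectivity" format="ascii">')
  w(paste(mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
          mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L))
  w('    </DataArray>',
    '    <DataArray type="Int64" Name="offsets" format="ascii">')
  w(sprintf("%d", 4L * seq_len(e)))
  w('    </DataArray>',
    '    <DataArray type="UInt8" Name="types" format="ascii">')
  w(sprintf("%d", rep(10L, e)))
  w('    </DataArray>', '   </Cells>', '   <CellData>')
  w('    <DataArray type="Int32" Name="region" format="ascii">')
  w(sprintf("%d", mesh$region))
  w('    </DataArray>')
  for (nm in names(cell_data)) {
    w(sprintf('    <DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(fmt_g(cell_data[[nm]]))
    w('    </DataArray>')
  }
  w('   </CellData>', '   <PointData>')
  for (nm in names(mesh$node_sets)) {
    mask <- integer(n)
    mask[mesh$node_sets[[nm]]] <- 1L
    w(sprintf('    <DataArray type="Int32" Name="nodeset_%s" format="ascii">', nm))
    w(sprintf("%d", mask))
    w('    </DataArray>')
  }
  w('   </PointData>', '  </Piece>', ' </UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("VTU file has no <Piece>")
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  coords <- matrix(num(pts), ncol = 3, byrow = TRUE)
  conn <- xml2::xml_find_first(piece, ".//Cells/DataArray[@Name='connectivity']")
  types <- xml2::xml_find_first(piece, ".//Cells/DataArray[@Name='types']")
  if (!all(num(types) == 10)) stop("VTU file contains non-tetrahedral cells")
  tets <- matrix(as.integer(num(conn)), ncol = 4, byrow = TRUE) + 1L
  reg_node <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='region']")
  if (inherits(reg_node, "xml_missing")) {
    stop("VTU file lacks the required integer cell-data array 'region'")
  }
  region <- as.integer(num(reg_node))
  node_sets <- list()
  for (da in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    if (!is.na(nm) && startsWith(nm, "nodeset_")) {
      node_sets[[sub("^nodeset_", "", nm)]] <- which(num(da) != 0)
    }
  }
  new_fh_mesh(coords, tets, region, node_sets)
}

#' Write a per-day field snapshot
#'
#' Writes a VTU snapshot with per-element Young's modulus, Poisson ratio and
#' strain invariants as cell data (`E`, `nu`, `eps_hyd`, `eps_dis`).
#'
#' @param mesh An `fh_mesh`.
#' @param path Output `.vtu` path.
#' @param E,nu Per-element material fields (MPa, unitless).
#' @param eps_hyd,eps_dis Optional per-element strain invariants
#'   (dimensionless); elements outside the callus may carry `NA`.
#' @return `path`, invisibly.
#' @export
write_field_vtu <- function(mesh, path, E, nu, eps_hyd = NULL, eps_dis = NULL) {
  cd <- list(E = E, nu = nu)
  if (!is.null(eps_hyd)) cd$eps_hyd <- eps_hyd
  if (!is.null(eps_dis)) cd$eps_dis <- eps_dis
  for (nm in names(cd)) {
    if (length(cd[[nm]]) != nrow(mesh$tets)) {
      stop(sprintf("cell data '%s' must have one value per element", nm))
    }
  }
  write_vtu(mesh, path, cell_data = cd)
  invisible(path)
}
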