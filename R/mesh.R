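# Structured hexahedral box meshes with named node/face sets and
# legacy-VTK / CSV export. Coordinates are mm; node indexing is 1-based in
# R structures (kernels receive 0-based copies).

axis_breaks <- function(L, h) {
  if (h <= 0) stop("element size h must be positive")
  # h > L collapses the axis to a single remainder element of size L
  if (h > L) return(c(0, L))
  n <- floor(L / h + 1e-8)
  rem <- L - n * h
  if (rem > 1e-8 * max(L, 1)) {
    b <- c((0:n) * h, L)           # n uniform elements plus one remainder
  } else {
    b <- (0:n) * h
    b[n + 1] <- L                  # snap to the exact length
  }
  b
}

#' Build a structured hexahedral box mesh
#'
#' Each axis is partitioned into `floor(L/h)` elements of size `h` plus one
#' smaller remainder element when `L` is not an integer multiple of `h`
#' (boundary elements shrink to fit the geometry). The Q2 family inserts
#' mid-edge/face/center nodes on the same partition. Node and face sets for
#' the six outer faces (`xmin`, `xmax`, ..., `zmax`) are generated
#' automatically.
#'
#' @param dimensions numeric length-3, box edge lengths (mm).
#' @param h target element size (mm).
#' @param family element family name or object (`"Q1"`, `"Q2"`, `"Q1NC"`).
#'   Q1 and Q1NC share the same 8-node geometry.
#' @return A `monofem_mesh` with `nodes` (N x 3), `elems` (Nel x nodes per
#'   element, 1-based, canonical corner order), per-element `origin` and
#'   `size`, and the named `node_sets` / `face_sets`.
#' @examples
#' m <- build_box_mesh(c(25, 1, 1), h = 1)
#' nrow(m$nodes)   # 104
#' @export
build_box_mesh <- function(dimensions, h, family = "Q1") {
  family <- element_family(family)
  if (!is.numeric(dimensions) || length(dimensions) != 3 ||
      any(dimensions <= 0))
    stop("dimensions must be three positive lengths (mm)")
  br <- lapply(dimensions, axis_breaks, h = h)
  nel_ax <- vapply(br, length, 1L) - 1L
  nx <- nel_ax[1]; ny <- nel_ax[2]; nz <- nel_ax[3]
  eg <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                    KEEP.OUT.ATTRS = FALSE)

  if (family$name == "Q2") {
    fine <- lapply(br, function(b) {
      n <- length(b) - 1
      c(rbind(b[-(n + 1)], (b[-(n + 1)] + b[-1]) / 2), b[n + 1])
    })
    nnx <- length(fine[[1]]); nny <- length(fine[[2]]); nnz <- length(fine[[3]])
    nodes <- as.matrix(expand.grid(fine[[1]], fine[[2]], fine[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
    fid <- function(i, j, k) i + (j - 1) * nnx + (k - 1) * nnx * nny
    off <- as.matrix(expand.grid(0:2, 0:2, 0:2, KEEP.OUT.ATTRS = FALSE))
    elems <- matrix(0L, nrow(eg), 27L)
    for (l in 1:27)
      elems[, l] <- fid(2L * eg$i - 1L + off[l, 1],
                        2L * eg$j - 1L + off[l, 2],
                        2L * eg$k - 1L + off[l, 3])
  } else {
    nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
    nodes <- as.matrix(expand.grid(br[[1]], br[[2]], br[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
    iid <- function(i, j, k) i + (j - 1) * nnx + (k - 1) * nnx * nny
    elems <- cbind(iid(eg$i,      eg$j,      eg$k),
                   iid(eg$i + 1L, eg$j,      eg$k),
                   iid(eg$i + 1L, eg$j + 1L, eg$k),
                   iid(eg$i,      eg$j + 1L, eg$k),
                   iid(eg$i,      eg$j,      eg$k + 1L),
                   iid(eg$i + 1L, eg$j,      eg$k + 1L),
                   iid(eg$i + 1L, eg$j + 1L, eg$k + 1L),
                   iid(eg$i,      eg$j + 1L, eg$k + 1L))
  }
  dimnames(nodes) <- NULL
  storage.mode(elems) <- "integer"

  hx <- diff(br[[1]]); hy <- diff(br[[2]]); hz <- diff(br[[3]])
  elem_size <- cbind(hx[eg$i], hy[eg$j], hz[eg$k])
  elem_origin <- cbind(br[[1]][eg$i], br[[2]][eg$j], br[[3]][eg$k])

  # local face ids: 1/2 = xi1 -/+, 3/4 = xi2 -/+, 5/6 = xi3 -/+
  face_sets <- list(
    xmin = data.frame(elem = which(eg$i == 1L),  face = 1L),
    xmax = data.frame(elem = which(eg$i == nx),  face = 2L),
    ymin = data.frame(elem = which(eg$j == 1L),  face = 3L),
    ymax = data.frame(elem = which(eg$j == ny),  face = 4L),
    zmin = data.frame(elem = which(eg$k == 1L),  face = 5L),
    zmax = data.frame(elem = which(eg$k == nz),  face = 6L))
  tol <- 1e-9
  node_sets <- list(
    xmin = which(nodes[, 1] < tol),
    xmax = which(nodes[, 1] > dimensions[1] - tol),
    ymin = which(nodes[, 2] < tol),
    ymax = which(nodes[, 2] > dimensions[2] - tol),
    zmin = which(nodes[, 3] < tol),
    zmax = which(nodes[, 3] > dimensions[3] - tol))

  structure(list(nodes = nodes, elems = elems, family = family$name,
                 dimensions = dimensions, h = h, breaks = br,
                 elem_origin = elem_origin, elem_size = elem_size,
                 node_sets = node_sets, face_sets = face_sets),
            class = "monofem_mesh")
}

#' @export
print.monofem_mesh <- function(x, ...) {
  cat(sprintf("monofem mesh: %s, %d nodes, %d elements, box %s mm, h = %g\n",
              x$family, nrow(x$nodes), nrow(x$elems),
              paste(signif(x$dimensions, 6), collapse = " x "), x$h))
  invisible(x)
}

#' Axis-aligned box region
#' @param min,max numeric length-3 corners (mm), `min <= max` per axis.
#' @export
region_box <- function(min, max) {
  if (any(max < min)) stop("region_box requires min <= max on every axis")
  structure(list(type = "box", min = as.numeric(min), max = as.numeric(max)),
            class = "monofem_region")
}

#' Boundary-plane region selector
#' @param axis 1, 2, 3 or "x", "y", "z".
#' @param value plane coordinate (mm).
#' @param tol selection tolerance (mm).
#' @export
region_plane <- function(axis, value, tol = 1e-9) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (!axis %in% 1:3) stop("axis must be 1..3 or x/y/z")
  structure(list(type = "plane", axis = as.integer(axis),
                 value = as.numeric(value), tol = tol),
            class = "monofem_region")
}

as_region <- function(region) {
  if (inherits(region, "monofem_region")) return(region)
  if (is.list(region) && !is.null(region$type)) {
    if (region$type == "box") return(region_box(region$min, region$max))
    if (region$type == "plane")
      return(region_plane(region$axis, region$value,
                          if (is.null(region$tol)) 1e-9 else region$tol))
  }
  stop("cannot interpret region specification")
}

#' Select mesh nodes inside a region
#'
#' Closed-interval membership with a 1e-9 mm tolerance. An empty selection
#' is returned with a warning.
#'
#' @param mesh a `monofem_mesh`.
#' @param region a [region_box()] or [region_plane()].
#' @return integer vector of node indices.
#' @export
select_nodes <- function(mesh, region) {
  region <- as_region(region)
  nd <- mesh$nodes
  tol <- 1e-9
  keep <- if (region$type == "box") {
    nd[, 1] >= region$min[1] - tol & nd[, 1] <= region$max[1] + tol &
    nd[, 2] >= region$min[2] - tol & nd[, 2] <= region$max[2] + tol &
    nd[, 3] >= region$min[3] - tol & nd[, 3] <= region$max[3] + tol
  } else {
    abs(nd[, region$axis] - region$value) <= region$tol + tol
  }
  idx <- which(keep)
  if (length(idx) == 0L) warning("region selects no nodes")
  idx
}

# Boundary faces lying on an outer plane of the box.
select_faces <- function(mesh, region) {
  region <- as_region(region)
  if (region$type != "plane")
    stop("face selection requires a plane region")
  tol <- 1e-9
  d <- region$axis
  if (abs(region$value) <= tol) {
    mesh$face_sets[[c("xmin", "ymin", "zmin")[d]]]
  } else if (abs(region$value - mesh$dimensions[d]) <= tol) {
    mesh$face_sets[[c("xmax", "ymax", "zmax")[d]]]
  } else {
    stop("only the six outer boundary planes carry faces")
  }
}

nearest_node <- function(mesh, coord) {
  d2 <- (mesh$nodes[, 1] - coord[1])^2 + (mesh$nodes[, 2] - coord[2])^2 +
        (mesh$nodes[, 3] - coord[3])^2
  which.min(d2)
}

# 8 Q1 sub-cells of a 27-node lattice element (corner order per sub-cell
# matches the hexahedron convention), used for VTK export of Q2 meshes.
.q2_subcells <- local({
  l <- function(a, b, c) a + 3L * b + 9L * c + 1L
  out <- matrix(0L, 8L, 8L)
  s <- 1L
  for (c0 in 0:1) for (b0 in 0:1) for (a0 in 0:1) {
    out[s, ] <- c(l(a0, b0, c0), l(a0 + 1L, b0, c0),
                  l(a0 + 1L, b0 + 1L, c0), l(a0, b0 + 1L, c0),
                  l(a0, b0, c0 + 1L), l(a0 + 1L, b0, c0 + 1L),
                  l(a0 + 1L, b0 + 1L, c0 + 1L), l(a0, b0 + 1L, c0 + 1L))
    s <- s + 1L
  }
  out
})

#' Write a mesh and nodal scalar fields as a legacy VTK file
#'
#' Emits an ASCII `DATASET UNSTRUCTURED_GRID` file. Q1/Q1NC elements are
#' written as linear hexahedra (cell type 12). Q2 elements are decomposed
#' into eight linear hexahedral sub-cells built from the 27-node lattice,
#' which keeps the file readable by any VTK tool without relying on the
#' triquadratic cell type.
#'
#' @param mesh a `monofem_mesh`.
#' @param point_fields named list of nodal scalar vectors (one value per
#'   mesh node).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, point_fields = list(), path) {
  n <- nrow(mesh$nodes)
  for (nm in names(point_fields))
    if (length(point_fields[[nm]]) != n)
      stop("field '", nm, "' has length ", length(point_fields[[nm]]),
           ", expected ", n)
  if (mesh$family == "Q2") {
    # rows of .q2_subcells index the local 27-node lattice; map to global ids
    cells <- do.call(rbind, lapply(seq_len(nrow(mesh$elems)), function(e)
      t(apply(.q2_subcells, 1L, function(loc) mesh$elems[e, loc]))))
  } else {
    cells <- mesh$elems
  }
  ncell <- nrow(cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "monofem unstructured grid",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ncell, 9L * ncell), con)
  writeLines(paste(8L, apply(cells - 1L, 1L, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(rep("12", ncell), con)
  if (length(point_fields)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.numeric(point_fields[[nm]])), con)
    }
  }
  invisible(path)
}

# Minimal legacy-VTK reader used for round-trip checks (points, cells and
# point scalars of files this package writes).
read_vtk_legacy <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- matrix(scan(text = ln[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  ncell <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cells <- lapply(ln[(ic + 1):(ic + ncell)], function(s)
    as.integer(strsplit(trimws(s), " +")[[1]][-1]) + 1L)
  fields <- list()
  for (is in grep("^SCALARS", ln)) {
    nm <- strsplit(ln[is], " ")[[1]][2]
    fields[[nm]] <- scan(text = ln[(is + 2):(is + 1 + np)], quiet = TRUE)
  }
  list(points = pts, cells = cells, fields = fields)
}

#' Write a nodal scalar field as CSV
#'
#' Columns: `node` (1-based id), `x`, `y`, `z` (mm) and `value`.
#' @param mesh a `monofem_mesh`.
#' @param values numeric vector, one value per node.
#' @param path output file path.
#' @param value_name column name for the values.
#' @export
write_node_csv <- function(mesh, values, path, value_name = "value") {
  if (length(values) != nrow(mesh$nodes))
    stop("values must have one entry per mesh node")
  df <- data.frame(node = seq_len(nrow(mesh$nodes)),
                   x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                   z = mesh$nodes[, 3], value = values)
  names(df)[5] <- value_name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Total mesh volume from the per-element sizes (structured boxes).
mesh_volume <- function(mesh) sum(apply(mesh$elem_size, 1, prod))
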