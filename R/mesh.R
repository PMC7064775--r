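#' Cell meshes: polygon outlines with pole coordinates
#'
#' A mesh set is a data frame with one row per polygon vertex
#' (`cell_id`, `vertex_index`, `x_um`, `y_um`) and an attached `poles`
#' data frame (`cell_id`, `pole`, `x_um`, `y_um`) giving the two pole tips
#' that define the long axis. The pole order fixes the orientation of the
#' standardized-cell projection (no axis mirroring).
#'
#' @name cell-mesh
NULL

#' Build a spherocylinder cell mesh
#'
#' Creates the polygon outline (projected spherocylinder: rectangle with
#' semicircular caps) of one cell, centered at `center` and rotated by
#' `angle` radians.
#'
#' @param center numeric (x, y), um.
#' @param length,width cell length (pole to pole) and width, um.
#' @param angle orientation of the long axis, radians.
#' @param cell_id integer id.
#' @param n_cap vertices per semicircular cap.
#' @return mesh data frame (see [cell-mesh]) for a single cell.
#' @export
make_cell_mesh <- function(center, length = 3, width = 1, angle = 0,
                           cell_id = 1L, n_cap = 16L) {
  stopifnot(length >= width, width > 0)
  R <- width / 2
  hl <- length / 2 - R          # half length of the cylindrical part
  th1 <- seq(-pi / 2, pi / 2, length.out = n_cap)    # right cap
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = n_cap) # left cap
  xs <- c(hl + R * cos(th1), -hl + R * cos(th2))
  ys <- c(R * sin(th1), R * sin(th2))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- cbind(xs, ys) %*% t(rot)
  poles_local <- rbind(c(-length / 2, 0), c(length / 2, 0))
  poles_xy <- poles_local %*% t(rot)
  mesh <- data.frame(cell_id = as.integer(cell_id),
                     vertex_index = seq_along(xs),
                     x_um = xy[, 1] + center[1],
                     y_um = xy[, 2] + center[2])
  poles <- data.frame(cell_id = as.integer(cell_id), pole = 1:2,
                      x_um = poles_xy[, 1] + center[1],
                      y_um = poles_xy[, 2] + center[2])
  attr(mesh, "poles") <- poles
  class(mesh) <- c("smt_mesh", "data.frame")
  mesh
}

#' Combine single-cell meshes into a mesh set
#' @param ... mesh objects from [make_cell_mesh()], or a single list of them.
#' @return combined mesh data frame with a combined `poles` attribute.
#' @export
mesh_set <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !is.data.frame(ms[[1]]))
    ms <- ms[[1]]
  if (length(ms) == 0L) {
    out <- data.frame(cell_id = integer(), vertex_index = integer(),
                      x_um = numeric(), y_um = numeric())
    attr(out, "poles") <- data.frame(cell_id = integer(), pole = integer(),
                                     x_um = numeric(), y_um = numeric())
    class(out) <- c("smt_mesh", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(ms, function(m) as.data.frame(m)))
  poles <- do.call(rbind, lapply(ms, function(m) attr(m, "poles")))
  rownames(out) <- rownames(poles) <- NULL
  attr(out, "poles") <- poles
  class(out) <- c("smt_mesh", "data.frame")
  out
}

mesh_poles <- function(meshes) {
  p <- attr(meshes, "poles")
  if (is.null(p)) stop("mesh set carries no pole coordinates")
  p
}

mesh_cell_ids <- function(meshes) unique(meshes$cell_id)

mesh_polygon <- function(meshes, cell) {
  m <- meshes[meshes$cell_id == cell, , drop = FALSE]
  if (nrow(m) == 0L) stop("unknown cell_id: ", cell)
  as.matrix(m[order(m$vertex_index), c("x_um", "y_um")])
}

#' Cell length from pole coordinates
#' @param meshes mesh set.
#' @return data frame `cell_id`, `length_um`.
#' @export
mesh_cell_lengths <- function(meshes) {
  p <- mesh_poles(meshes)
  ids <- unique(p$cell_id)
  len <- vapply(ids, function(id) {
    q <- p[p$cell_id == id, ]
    sqrt(diff(q$x_um)^2 + diff(q$y_um)^2)
  }, numeric(1))
  data.frame(cell_id = ids, length_um = len)
}

#' Write / read a mesh set as plain CSV
#'
#' Vertices and poles share one file; pole rows carry `type = "pole"` and
#' `vertex_index` 1 or 2.
#'
#' @param meshes mesh set.
#' @param path CSV path.
#' @export
write_mesh_csv <- function(meshes, path) {
  v <- data.frame(cell_id = meshes$cell_id, type = "outline",
                  vertex_index = meshes$vertex_index,
                  x_um = meshes$x_um, y_um = meshes$y_um)
  p <- mesh_poles(meshes)
  pv <- data.frame(cell_id = p$cell_id, type = "pole", vertex_index = p$pole,
                   x_um = p$x_um, y_um = p$y_um)
  utils::write.csv(rbind(v, pv), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_csv
#' @param path CSV path written by [write_mesh_csv()].
#' @export
read_mesh_csv <- function(path) {
  d <- utils::read.csv(path)
  v <- d[d$type == "outline", ]
  out <- data.frame(cell_id = as.integer(v$cell_id),
                    vertex_index = as.integer(v$vertex_index),
                    x_um = v$x_um, y_um = v$y_um)
  p <- d[d$type == "pole", ]
  attr(out, "poles") <- data.frame(cell_id = as.integer(p$cell_id),
                                   pole = as.integer(p$vertex_index),
                                   x_um = p$x_um, y_um = p$y_um)
  class(out) <- c("smt_mesh", "data.frame")
  out
}

# Points-in-polygon for one cell polygon (closed implicitly).
points_in_polygon <- function(xy, poly) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), xy)
}
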