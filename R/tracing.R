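# SWC tracings: I/O, 3D Sholl analysis against concentric spheres around the
# soma, branch metrics (primary branches, ramification index, mean branch
# length) and the endpoint-circumscribed domain area.

#' Construct a tracing from SWC-style node records
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent` (coordinates in micrometers, `parent == -1` for the root).
#' @param soma_center Optional `(x, y, z)`; default the root node coordinates.
#' @return An object of class `tracing`.
#' @export
tracing <- function(nodes, soma_center = NULL) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) stop("nodes must have SWC columns")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) stop("tracing must have exactly one root (parent -1)")
  if (any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node coordinates must be finite")
  idx <- match(nodes$parent, nodes$id)
  if (any(is.na(idx[-roots]))) stop("parent ids must resolve to node ids")
  if (is.null(soma_center))
    soma_center <- as.numeric(nodes[roots, c("x", "y", "z")])
  structure(list(nodes = nodes, root = roots, parent_idx = idx,
                 soma_center = soma_center),
            class = "tracing")
}

#' @export
print.tracing <- function(x, ...) {
  cat(sprintf("<tracing> %d nodes, %d segments\n",
              nrow(x$nodes), sum(x$nodes$parent != -1)))
  invisible(x)
}

#' Read an SWC file
#'
#' Space-separated SWC with `#` comments, columns
#' id type x y z radius parent, coordinates in micrometers.
#'
#' @param path SWC file path.
#' @param soma_center Optional override of the soma center.
#' @return A [tracing()].
#' @export
read_swc <- function(path, soma_center = NULL) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("id", "type", "x", "y", "z",
                                       "radius", "parent"))
  tracing(d, soma_center = soma_center)
}

#' Write a tracing to an SWC file
#'
#' @param trc A [tracing()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trc, path) {
  stopifnot(inherits(trc, "tracing"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  utils::write.table(trc$nodes[, c("id", "type", "x", "y", "z",
                                   "radius", "parent")],
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Segment endpoint matrices (parent row, child row) in tracing order.
tracing_segments <- function(trc) {
  sel <- which(trc$nodes$parent != -1)
  p <- trc$parent_idx[sel]
  list(
    from = as.matrix(trc$nodes[p, c("x", "y", "z")]),
    to = as.matrix(trc$nodes[sel, c("x", "y", "z")]),
    child = sel, parent = p
  )
}

#' 3D Sholl analysis of a tracing
#'
#' Counts, for every radius, how many times tracing segments (straight
#' parent-to-child lines) cross the sphere of that radius centered on the
#' soma. Crossings are counted exactly from the quadratic distance function
#' along each segment, so a segment dipping through a sphere and back counts
#' twice. A point exactly at distance r is treated as outside (>= r).
#'
#' @param trc A [tracing()].
#' @param radii Strictly increasing radii in micrometers (default 10-100 um,
#'   step 1).
#' @return An object of class `sholl_profile` with `radii` and
#'   `intersections`.
#' @export
sholl_3d <- function(trc, radii = 10:100) {
  stopifnot(inherits(trc, "tracing"))
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  seg <- tracing_segments(trc)
  if (length(seg$child) == 0) {
    warning("tracing has no segments; Sholl profile is all zero")
    return(structure(list(radii = as.numeric(radii),
                          intersections = integer(length(radii))),
                     class = "sholl_profile"))
  }
  c0 <- trc$soma_center
  P <- sweep(seg$from, 2, c0)
  Q <- sweep(seg$to, 2, c0)
  D <- Q - P
  a <- rowSums(D^2)
  b <- 2 * rowSums(P * D)
  d0 <- sqrt(rowSums(P^2))          # distance at t = 0
  d1 <- sqrt(rowSums(Q^2))          # distance at t = 1
  tstar <- ifelse(a > 0, -b / (2 * a), 0)
  fmin <- pmin(d0, d1)
  interior <- a > 0 & tstar > 0 & tstar < 1
  fmin[interior] <- sqrt(pmax(rowSums(P^2)[interior] -
                                b[interior]^2 / (4 * a[interior]), 0))
  counts <- vapply(radii, function(r) {
    out0 <- d0 >= r
    out1 <- d1 >= r
    sum(ifelse(xor(out0, out1), 1L,
               ifelse(out0 & out1 & fmin < r, 2L, 0L)))
  }, numeric(1))
  structure(list(radii = as.numeric(radii), intersections = as.integer(counts)),
            class = "sholl_profile")
}

# Children index list by node.
children_of <- function(trc) {
  n <- nrow(trc$nodes)
  kids <- vector("list", n)
  sel <- which(trc$nodes$parent != -1)
  for (i in sel) {
    p <- trc$parent_idx[i]
    kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

# Decompose the tree into branches: maximal unbranched paths starting at the
# root's children or at a fork's children and ending at the next fork or tip.
branch_paths <- function(trc) {
  kids <- children_of(trc)
  xyz <- as.matrix(trc$nodes[, c("x", "y", "z")])
  seglen <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  starts <- unlist(lapply(c(trc$root,
                            which(vapply(kids, length, 1L) >= 2)),
                          function(v) kids[[v]]))
  starts <- unique(starts)
  lapply(starts, function(s) {
    len <- seglen(trc$parent_idx[s], s)
    cur <- s
    path <- c(trc$parent_idx[s], s)
    while (length(kids[[cur]]) == 1) {
      nxt <- kids[[cur]][1]
      len <- len + seglen(cur, nxt)
      path <- c(path, nxt)
      cur <- nxt
    }
    list(nodes = path, length = len, terminal = length(kids[[cur]]) == 0)
  })
}

#' Branch metrics of a tracing
#'
#' * `n_primary_branches`: number of child subtrees of the root (soma) node.
#' * `max_intersections`: maximum of the Sholl profile.
#' * `ramification_index`: `max_intersections / n_primary_branches`.
#' * `mean_branch_length`: mean path length in micrometers over branches
#'   (root-to-fork, fork-to-fork and fork-to-tip paths).
#'
#' @param trc A [tracing()].
#' @param profile A [sholl_3d()] profile computed from `trc`.
#' @return A list of class `morpho_metrics`.
#' @export
branch_metrics <- function(trc, profile = sholl_3d(trc)) {
  stopifnot(inherits(trc, "tracing"), inherits(profile, "sholl_profile"))
  kids <- children_of(trc)
  n_primary <- length(kids[[trc$root]])
  if (n_primary == 0) stop("undefined ramification index: zero primary branches")
  paths <- branch_paths(trc)
  mx <- max(profile$intersections)
  structure(
    list(n_primary_branches = n_primary,
         max_intersections = mx,
         ramification_index = mx / n_primary,
         mean_branch_length = mean(vapply(paths, `[[`, numeric(1), "length")),
         n_branches = length(paths)),
    class = "morpho_metrics"
  )
}

# Shoelace area of an ordered polygon (two-column matrix).
shoelace_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

#' Domain area from process endpoints
#'
#' Projects the tracing's terminal nodes (tips) onto the (x, y) plane and
#' returns the area of the polygon connecting them, taken as the convex hull
#' of the tip projections (the unique vertex-order-free polygon).
#'
#' @param trc A [tracing()].
#' @return Area in square micrometers.
#' @export
domain_area_from_endpoints <- function(trc) {
  stopifnot(inherits(trc, "tracing"))
  kids <- children_of(trc)
  tips <- which(vapply(kids, length, 1L) == 0 &
                  seq_len(nrow(trc$nodes)) != trc$root)
  if (length(tips) < 3)
    stop("degenerate polygon: fewer than 3 terminal nodes")
  pts <- as.matrix(trc$nodes[tips, c("x", "y")])
  hull <- grDevices::chull(pts)
  if (length(hull) < 3)
    stop("degenerate polygon: tip projections are collinear")
  area <- shoelace_area(pts[hull, , drop = FALSE])
  if (area <= .Machine$double.eps * max(abs(pts))^2 * length(tips))
    stop("degenerate polygon: tip projections are collinear")
  area
}
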