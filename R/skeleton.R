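#' Topology-preserving 3D thinning
#'
#' Reduces the foreground of a label volume to a one-voxel-wide curve
#' skeleton by iterative deletion of simple points (voxels whose removal
#' changes neither the 26-connected foreground components nor the 6-connected
#' background components) from the six directional borders in the fixed
#' order U, D, N, S, E, W. Deletions are sequential, re-testing simplicity at
#' deletion time, so the component count and loop count (Betti-1) of the
#' input are preserved exactly. Curve endpoints (voxels with a single
#' foreground 26-neighbor) are retained.
#'
#' @param labels a `label_volume` (any positive label is foreground) or a 3D
#'   binary array.
#' @param voxel_size nm, required when `labels` is a bare array.
#' @return a `skeleton_volume`: list with `mask` (binary 3D array),
#'   `voxel_size`.
#' @export
thin3d <- function(labels, voxel_size = NULL) {
  if (inherits(labels, "label_volume")) {
    mask <- labels$labels > 0
    voxel_size <- labels$voxel_size
  } else {
    mask <- labels > 0
    if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
  }
  out <- cpp_thin3d(as.integer(mask), as.integer(dim(mask)))
  dim(out) <- dim(mask)
  structure(list(mask = out, voxel_size = voxel_size),
            class = "skeleton_volume")
}

NB26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
})

#' Build a graph from a curve skeleton
#'
#' Nodes are skeleton voxels of degree != 2 (endpoints, junctions); edges are
#' the simple voxel paths between them, with geodesic length in nm and a mean
#' orientation unit vector. Isolated cycles receive one artificial node
#' carrying a self-edge.
#'
#' @param skel a `skeleton_volume` from [thin3d()].
#' @return a `skeleton_graph`: list with `nodes` (data.frame id, z, y, x
#'   voxel coords, degree), `edges` (list of records with `n1`, `n2`, `path`
#'   voxel-coordinate matrix, `length_nm`, `orient`), `voxel_size`.
#' @export
build_skeleton_graph <- function(skel) {
  stopifnot(inherits(skel, "skeleton_volume"))
  mask <- skel$mask
  d <- dim(mask)
  vs <- skel$voxel_size
  idx <- which(mask != 0)
  n <- length(idx)
  if (n == 0)
    return(structure(list(nodes = data.frame(id = integer(), z = integer(),
                                             y = integer(), x = integer(),
                                             degree = integer()),
                          edges = list(), voxel_size = vs),
                     class = "skeleton_graph"))
  z <- (idx - 1) %% d[1]
  y <- ((idx - 1) %/% d[1]) %% d[2]
  x <- (idx - 1) %/% (d[1] * d[2])
  # 26-neighbor ordinals (n x 26, NA outside skeleton)
  nbr <- matrix(NA_integer_, n, 26)
  for (k in 1:26) {
    zz <- z + NB26[k, 1]; yy <- y + NB26[k, 2]; xx <- x + NB26[k, 3]
    ok <- zz >= 0 & zz < d[1] & yy >= 0 & yy < d[2] & xx >= 0 & xx < d[3]
    lin <- zz + d[1] * (yy + d[2] * xx) + 1
    m <- rep(NA_integer_, n)
    m[ok] <- match(lin[ok], idx)
    nbr[, k] <- m
  }
  deg <- rowSums(!is.na(nbr))
  if (any(deg >= 26))
    stop("not a skeleton: fully solid 3x3x3 neighborhood present")
  step_len <- sqrt(rowSums(NB26^2))

  is_node <- deg != 2
  node_of <- rep(NA_integer_, n)
  node_ord <- which(is_node)
  node_of[node_ord] <- seq_along(node_ord)
  edges <- list()
  # visited marks traversal of (voxel, neighbor-slot) half-steps
  used <- matrix(FALSE, n, 26)
  back_slot <- match(-(NB26[, 1] + 3 * NB26[, 2] + 9 * NB26[, 3]),
                     NB26[, 1] + 3 * NB26[, 2] + 9 * NB26[, 3])
  trace_path <- function(start, slot) {
    path <- start
    lens <- numeric(0)
    cur <- start
    s <- slot
    repeat {
      used[cur, s] <<- TRUE
      nxt <- nbr[cur, s]
      used[nxt, back_slot[s]] <<- TRUE
      lens <- c(lens, step_len[s])
      path <- c(path, nxt)
      if (is_node[nxt] || nxt == start) break
      slots <- which(!is.na(nbr[nxt, ]))
      fwd <- slots[nbr[nxt, slots] != cur]
      if (length(fwd) == 0) break          # shouldn't happen on deg-2
      s <- fwd[1]
      cur <- nxt
    }
    list(path = path, len = sum(lens))
  }
  add_edge <- function(tr) {
    p <- tr$path
    pm <- cbind(z = z[p], y = y[p], x = x[p])
    v <- pm[nrow(pm), ] - pm[1, ]
    o <- if (sum(v^2) > 0) unit3(as.numeric(v)) else {
      if (nrow(pm) > 2) {
        cn <- sweep(pm, 2, colMeans(pm))
        unit3(eigen(crossprod(cn), symmetric = TRUE)$vectors[, 1])
      } else c(0, 1, 0)
    }
    edges[[length(edges) + 1L]] <<- list(
      n1 = node_of[p[1]], n2 = node_of[p[length(p)]], path = pm,
      length_nm = max(tr$len, 1) * vs, orient = o)
  }
  for (v0 in node_ord) {
    for (s in which(!is.na(nbr[v0, ]))) {
      if (used[v0, s]) next
      tr <- trace_path(v0, s)
      add_edge(tr)
    }
  }
  # isolated cycles: deg-2 voxels never traversed
  remaining <- which(!is_node & deg > 0)
  for (v0 in remaining) {
    slots <- which(!is.na(nbr[v0, ]))
    if (all(used[v0, slots]) || length(slots) == 0) next
    node_of[v0] <- max(node_of, 0, na.rm = TRUE) + 1L
    is_node[v0] <- TRUE
    tr <- trace_path(v0, slots[1])
    add_edge(tr)
    is_node[v0] <- TRUE
  }
  node_ids <- which(!is.na(node_of))
  nodes <- data.frame(id = node_of[node_ids], z = z[node_ids],
                      y = y[node_ids], x = x[node_ids])
  nodes <- nodes[order(nodes$id), ]
  ndeg <- integer(nrow(nodes))
  for (e in edges) {
    ndeg[e$n1] <- ndeg[e$n1] + 1L
    if (e$n2 != e$n1) ndeg[e$n2] <- ndeg[e$n2] + 1L
  }
  nodes$degree <- ndeg
  structure(list(nodes = nodes, edges = edges, voxel_size = vs),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges, total length %.1f nm\n",
              nrow(x$nodes), length(x$edges),
              sum(vapply(x$edges, function(e) e$length_nm, numeric(1)))))
  invisible(x)
}

edge_lengths <- function(g) vapply(g$edges, function(e) e$length_nm, numeric(1))

node_degrees <- function(g) {
  nd <- integer(nrow(g$nodes))
  for (e in g$edges) {
    nd[e$n1] <- nd[e$n1] + 1L
    if (e$n2 != e$n1) nd[e$n2] <- nd[e$n2] + 1L
  }
  nd
}

# connected components of the graph over shared nodes
graph_components <- function(g) {
  ne <- length(g$edges)
  comp <- integer(ne)
  if (ne == 0) return(comp)
  nn <- nrow(g$nodes)
  parent <- seq_len(nn)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in g$edges) {
    a <- find(e$n1); b <- find(e$n2)
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  ids <- match(roots, unique(roots))
  vapply(g$edges, function(e) ids[e$n1], integer(1))
}

#' Prune short terminal spurs from a skeleton graph
#'
#' Thinning leaves short terminal twigs at surface irregularities. This
#' iteratively removes leaf edges shorter than `min_len`, then splices
#' the resulting degree-2 nodes, until a fixed point. The longest edge of
#' each connected component is protected, so no component ever vanishes.
#'
#' @param g a `skeleton_graph`.
#' @param min_len minimum retained leaf-edge length, nm (0 = identity).
#' @return pruned `skeleton_graph`.
#' @export
prune_spurs <- function(g, min_len) {
  stopifnot(inherits(g, "skeleton_graph"))
  if (min_len < 0) stop("min_len must be >= 0")
  if (min_len == 0 || length(g$edges) == 0) return(g)
  repeat {
    changed <- FALSE
    deg <- node_degrees(g)
    comp <- graph_components(g)
    lens <- edge_lengths(g)
    keep <- rep(TRUE, length(g$edges))
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      longest <- members[which.max(lens[members])]
      for (ei in members) {
        if (ei == longest) next
        e <- g$edges[[ei]]
        leaf <- (deg[e$n1] == 1) || (deg[e$n2] == 1)
        if (leaf && lens[ei] < min_len) {
          keep[ei] <- FALSE
          changed <- TRUE
          deg[e$n1] <- deg[e$n1] - 1L
          if (e$n2 != e$n1) deg[e$n2] <- deg[e$n2] - 1L
        }
      }
    }
    g$edges <- g$edges[keep]
    g <- splice_degree2(g)
    if (!changed) break
  }
  g$nodes$degree <- node_degrees(g)
  g
}

# merge chains through degree-2 nodes into single edges (single pass with
# incremental incidence bookkeeping)
splice_degree2 <- function(g) {
  ne <- length(g$edges)
  if (ne == 0) return(g)
  nn <- nrow(g$nodes)
  alive <- rep(TRUE, ne)
  inc <- vector("list", nn)
  for (ei in seq_len(ne)) {
    e <- g$edges[[ei]]
    inc[[e$n1]] <- c(inc[[e$n1]], ei)
    if (e$n2 != e$n1) inc[[e$n2]] <- c(inc[[e$n2]], ei)
  }
  for (nd in seq_len(nn)) {
    eis <- unique(inc[[nd]])
    eis <- eis[alive[eis]]
    if (length(eis) != 2) next
    e1 <- g$edges[[eis[1]]]; e2 <- g$edges[[eis[2]]]
    if (e1$n1 == e1$n2 || e2$n1 == e2$n2) next
    # orient e1 to end at nd, e2 to start at nd
    p1 <- e1$path
    if (e1$n1 == nd) { p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]; a <- e1$n2 } else a <- e1$n1
    p2 <- e2$path
    if (e2$n2 == nd) { p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]; b <- e2$n1 } else b <- e2$n2
    path <- rbind(p1, p2[-1, , drop = FALSE])
    v <- path[nrow(path), ] - path[1, ]
    o <- if (sum(v^2) > 0) unit3(as.numeric(v)) else e1$orient
    g$edges[[eis[1]]] <- list(n1 = a, n2 = b, path = path,
                              length_nm = e1$length_nm + e2$length_nm,
                              orient = o)
    alive[eis[2]] <- FALSE
    inc[[b]][inc[[b]] == eis[2]] <- eis[1]
    inc[[nd]] <- integer(0)
  }
  g$edges <- g$edges[alive]
  g
}

#' Classify skeleton segments into fibrils and cross-links
#'
#' Fibrils are maximal chains of edges, aligned within `align_cone` of the
#' dominant network orientation, with total length at least
#' `fibril_min_length`. Cross-links are edges no longer than
#' `crosslink_max_length` whose two ends attach to two distinct fibrils
#' (with a measured surface-to-surface length of at least
#' `crosslink_min_length`, excluding direct fibril-fibril contacts). Edges
#' matching neither class are counted as unclassified. Per-vertex fibril
#' radii come from the Euclidean distance transform of the segmentation.
#' Fibrils are assigned to lamellae by splitting the sorted fibril center
#' heights (beam-axis coordinate) at jumps larger than `layer_split_gap`.
#'
#' @param g a pruned `skeleton_graph`.
#' @param labels the `label_volume` the skeleton came from.
#' @param params list; see [classify_params()].
#' @param meas_mask optional binary array at the measurement (half-maximum)
#'   level; radii are taken from its distance transform, so detection can
#'   be generous while radii stay calibrated. Defaults to `labels > 0`.
#' @param intensity optional filtered intensity array; with `core_level`,
#'   fibril chains whose median on-skeleton intensity falls below
#'   `core_level` are rejected as reconstruction artifacts (missing-wedge
#'   sidelobes, noise ridges) and counted as unclassified.
#' @param core_level intensity validation level (SD units).
#' @return a `wall_network`: list with `fibrils` (each: path voxel matrix,
#'   radii_nm, orient, length_nm, layer), `crosslinks` (each: path, fibril_i,
#'   fibril_j, path_length_nm, length_nm surface-to-surface),
#'   `n_unclassified`, `dominant`, `voxel_size`.
#' @export
classify_segments <- function(g, labels, params = classify_params(),
                              meas_mask = NULL, intensity = NULL,
                              core_level = NULL) {
  stopifnot(inherits(g, "skeleton_graph"), inherits(labels, "label_volume"))
  vs <- g$voxel_size
  if (is.null(meas_mask)) meas_mask <- labels$labels > 0
  edt <- cpp_edt3d(as.integer(meas_mask), as.integer(dim(labels$labels)))
  dim(edt) <- dim(labels$labels)
  ne <- length(g$edges)
  empty <- structure(list(fibrils = list(), crosslinks = list(),
                          n_unclassified = ne, dominant = c(0, 1, 0),
                          voxel_size = vs), class = "wall_network")
  if (ne == 0) {
    warning("no fibrils found: empty skeleton graph")
    return(empty)
  }
  lens <- edge_lengths(g)
  ors <- t(vapply(g$edges, function(e) e$orient, numeric(3)))
  # dominant orientation from length-weighted orientation outer products
  M <- matrix(0, 3, 3)
  for (i in seq_len(ne)) M <- M + lens[i] * tcrossprod(ors[i, ])
  dom <- eigen(M, symmetric = TRUE)$vectors[, 1]
  dom <- fix_sign(dom)
  cosang <- abs(ors %*% dom)
  aligned <- cosang >= cos(params$align_cone * pi / 180)

  # grow fibril chains from aligned edges, longest first
  inc <- lapply(seq_len(nrow(g$nodes)), function(i) integer(0))
  for (ei in seq_len(ne)) {
    e <- g$edges[[ei]]
    inc[[e$n1]] <- c(inc[[e$n1]], ei)
    if (e$n2 != e$n1) inc[[e$n2]] <- c(inc[[e$n2]], ei)
  }
  used <- rep(FALSE, ne)
  chains <- list()
  for (start in order(-lens)) {
    if (used[start] || !aligned[start]) next
    chain <- start
    used[start] <- TRUE
    for (endk in 1:2) {
      e <- g$edges[[start]]
      node <- if (endk == 1) e$n1 else e$n2
      prev_ei <- start
      repeat {
        cands <- setdiff(inc[[node]], prev_ei)
        cands <- cands[!used[cands] & aligned[cands]]
        if (!length(cands)) break
        pe <- g$edges[[prev_ei]]
        co <- abs(vapply(cands, function(ci)
          sum(g$edges[[ci]]$orient * pe$orient), numeric(1)))
        nxt <- cands[which.max(co)]
        used[nxt] <- TRUE
        chain <- if (endk == 1) c(nxt, chain) else c(chain, nxt)
        en <- g$edges[[nxt]]
        node <- if (en$n1 == node) en$n2 else en$n1
        prev_ei <- nxt
      }
    }
    chains[[length(chains) + 1L]] <- chain
  }
  fibrils <- list()
  edge_fibril <- rep(NA_integer_, ne)
  cands <- list()
  for (ch in chains) {
    tot <- sum(lens[ch])
    if (tot < params$fibril_min_length) { used[ch] <- FALSE; next }
    path <- chain_path(g, ch)
    medI <- NA_real_
    if (!is.null(intensity)) {
      vals <- intensity[path[, 1] + 1 + dim(intensity)[1] *
                          (path[, 2] + dim(intensity)[2] * path[, 3])]
      medI <- stats::median(vals)
    }
    cands[[length(cands) + 1L]] <- list(path = path, length_nm = tot,
                                        edge_ids = ch, medI = medI,
                                        prox = prox_profile(path))
  }
  # duplicate suppression: the missing wedge elongates cross-sections along
  # the beam axis, and thinning can leave parallel strands inside one
  # elongated fibril. Greedily keep the longest chain; drop any shorter
  # chain tracking an accepted one within a window tight in-plane and
  # generous along the beam axis.
  ord2 <- order(-vapply(cands, function(cc) cc$length_nm, numeric(1)))
  accepted <- list()
  consumed <- rep(FALSE, ne)
  for (ci in ord2) {
    cc <- cands[[ci]]
    dup <- FALSE
    for (acc in accepted) {
      pr <- path_proximity(cc$prox, acc$prox)
      if (!is.null(pr) && pr["overlap"] >= 0.5 &&
          (pr["dx"] * vs / 4.5)^2 + (pr["dz"] * vs / 6.5)^2 < 1) {
        dup <- TRUE
        break
      }
    }
    if (dup) { consumed[cc$edge_ids] <- TRUE; next }
    accepted[[length(accepted) + 1L]] <- cc
  }
  # ghost-replica filter: missing-wedge ringing copies a bright fibril to
  # dim parallel strands further along the beam axis. A dim chain (below
  # core_level) running near a much brighter accepted chain is such a
  # replica; dim but isolated chains are genuine and kept.
  if (!is.null(intensity) && !is.null(core_level) && length(accepted) > 1) {
    keep2 <- rep(TRUE, length(accepted))
    for (i in seq_along(accepted)) {
      f <- accepted[[i]]
      if (is.na(f$medI) || f$medI >= core_level) next
      for (j in seq_along(accepted)) {
        if (j == i || !keep2[j]) next
        gacc <- accepted[[j]]
        if (is.na(gacc$medI) ||
            gacc$medI < max(2 * f$medI, core_level)) next
        pr <- path_proximity(f$prox, gacc$prox)
        if (!is.null(pr) && pr["overlap"] >= 0.3 &&
            pr["dx"] * vs < 6 && pr["dz"] * vs < 14) {
          keep2[i] <- FALSE
          consumed[f$edge_ids] <- TRUE
          break
        }
      }
    }
    accepted <- accepted[keep2]
  }
  for (cc in accepted) {
    path <- cc$path
    # EDT measures to the nearest background voxel center, half a voxel
    # beyond the surface
    radii <- pmax((edt[path[, 1] + 1 + dim(edt)[1] *
                         (path[, 2] + dim(edt)[2] * path[, 3])] - 0.5) * vs,
                  0.4 * vs)
    v <- path[nrow(path), ] - path[1, ]
    o <- if (sum(v^2) > 0) fix_sign(unit3(as.numeric(v))) else dom
    fid <- length(fibrils) + 1L
    fibrils[[fid]] <- list(path = path, radii_nm = radii, orient = o,
                           length_nm = cc$length_nm, layer = NA_integer_,
                           edge_ids = cc$edge_ids, medI = cc$medI)
    edge_fibril[cc$edge_ids] <- fid
  }
  if (!length(fibrils)) {
    warning("no fibrils found")
    empty$n_unclassified <- sum(is.na(edge_fibril))
    return(empty)
  }
  # lamella assignment: split sorted center heights at large jumps
  zc <- vapply(fibrils, function(f) mean(f$path[, 1]) * vs, numeric(1))
  ord <- order(zc)
  layer <- integer(length(zc))
  cur <- 1L
  layer[ord[1]] <- 1L
  if (length(ord) > 1) for (i in 2:length(ord)) {
    if (zc[ord[i]] - zc[ord[i - 1]] > params$layer_split_gap) cur <- cur + 1L
    layer[ord[i]] <- cur
  }
  for (i in seq_along(fibrils)) fibrils[[i]]$layer <- layer[i]

  # node -> fibril attachment
  node_fib <- lapply(seq_len(nrow(g$nodes)), function(i) integer(0))
  for (ei in which(!is.na(edge_fibril))) {
    e <- g$edges[[ei]]
    f <- edge_fibril[ei]
    node_fib[[e$n1]] <- union(node_fib[[e$n1]], f)
    node_fib[[e$n2]] <- union(node_fib[[e$n2]], f)
  }
  # bridges: connected components of the residual (non-fibril) edges; a
  # component attaching to exactly two distinct fibrils is a cross-link
  # candidate, measured along the shortest residual path between the two
  # attachment junctions
  res <- which(is.na(edge_fibril) & !consumed)
  crosslinks <- list()
  n_uncl <- 0L
  if (length(res)) {
    rcomp <- residual_components(g, res)
    for (cmp in rcomp) {
      nds <- unique(unlist(lapply(cmp, function(ei)
        c(g$edges[[ei]]$n1, g$edges[[ei]]$n2))))
      att <- unique(unlist(node_fib[nds]))
      ok <- FALSE
      if (length(att) == 2) {
        a <- att[1]; b <- att[2]
        na_ <- nds[vapply(nds, function(nd) a %in% node_fib[[nd]], logical(1))]
        nb_ <- nds[vapply(nds, function(nd) b %in% node_fib[[nd]], logical(1))]
        sp <- residual_shortest_path(g, cmp, na_, nb_)
        if (!is.null(sp)) {
          # junction nodes sit where the bridge meets the fibril skeleton,
          # slightly off the centerline; project each onto its fibril's
          # local centerline so the chord measures center to center
          pa <- fibril_point_near(fibrils[[a]],
                                  as.numeric(g$nodes[sp$from, c("z", "y", "x")]))
          pb <- fibril_point_near(fibrils[[b]],
                                  as.numeric(g$nodes[sp$to, c("z", "y", "x")]))
          chord <- sqrt(sum((pa - pb)^2)) * vs
          ra <- fibril_radius_near(fibrils[[a]], pa, vs)
          rb <- fibril_radius_near(fibrils[[b]], pb, vs)
          ell <- chord - ra - rb
          same_lamella <- abs(pa[1] - pb[1]) * vs <= params$crosslink_max_dz
          anchored <- min(ra, rb) >= params$crosslink_min_anchor
          # a bridge joins neighbors side by side: its chord runs transverse
          # to the fibril axis. A near-axial chord is a noise connector
          # between two fragments of one broken fibril.
          chordv <- pb - pa
          transverse <- sqrt(sum(chordv^2)) > 0 &&
            abs(sum(chordv * dom)) / sqrt(sum(chordv^2)) <= 0.75
          # ghost-replica strands that slip through the fibril filters are
          # dim; a credible bridge anchors on two unambiguous (bright)
          # fibrils
          bright_hosts <- is.null(core_level) ||
            (isTRUE(fibrils[[a]]$medI >= core_level) &&
               isTRUE(fibrils[[b]]$medI >= core_level))
          if (same_lamella && anchored && bright_hosts && transverse &&
              chord <= params$crosslink_max_length &&
              ell >= params$crosslink_min_length) {
            crosslinks[[length(crosslinks) + 1L]] <-
              list(path = do.call(rbind, lapply(sp$edges, function(ei)
                g$edges[[ei]]$path)),
                fibril_i = a, fibril_j = b, end_a = pa, end_b = pb,
                r_a = ra, r_b = rb,
                path_length_nm = chord, length_nm = ell)
            ok <- TRUE
          }
        }
      }
      if (!ok) n_uncl <- n_uncl + length(cmp)
    }
  }
  structure(list(fibrils = fibrils, crosslinks = crosslinks,
                 n_unclassified = n_uncl, dominant = dom, voxel_size = vs),
            class = "wall_network")
}

#' Classification parameters
#'
#' @param fibril_min_length minimum fibril chain length, nm.
#' @param crosslink_max_length maximum cross-link skeleton-path length, nm.
#' @param crosslink_min_length minimum surface-to-surface cross-link length,
#'   nm; excludes direct fibril contacts.
#' @param crosslink_max_dz maximum beam-axis height difference (nm) of the
#'   two attachment junctions: cross-links join neighboring fibrils within a
#'   lamella, and apparent vertical bridges between lamellae are
#'   missing-wedge elongation artifacts.
#' @param crosslink_min_anchor minimum local fibril radius (nm) at both
#'   attachment junctions; bridges anchored in sub-resolution wisps are
#'   noise artifacts.
#' @param align_cone half-angle (degrees) of the cone about the dominant
#'   orientation within which edges count as fibril material.
#' @param layer_split_gap minimum height jump (nm) separating two lamellae.
#' @return parameter list.
#' @export
classify_params <- function(fibril_min_length = 20, crosslink_max_length = 15,
                            crosslink_min_length = 1.8, crosslink_max_dz = 3.5,
                            crosslink_min_anchor = 0.7, align_cone = 45,
                            layer_split_gap = 4) {
  list(fibril_min_length = fibril_min_length,
       crosslink_max_length = crosslink_max_length,
       crosslink_min_length = crosslink_min_length,
       crosslink_max_dz = crosslink_max_dz,
       crosslink_min_anchor = crosslink_min_anchor,
       align_cone = align_cone, layer_split_gap = layer_split_gap)
}

#' @export
print.wall_network <- function(x, ...) {
  cat(sprintf("<wall_network> %d fibrils, %d cross-links, %d unclassified edges\n",
              length(x$fibrils), length(x$crosslinks), x$n_unclassified))
  invisible(x)
}

fix_sign <- function(v) {
  for (j in seq_along(v)) if (abs(v[j]) > 1e-12) {
    if (v[j] < 0) v <- -v
    break
  }
  v
}

# concatenate edge paths of a chain into one polyline (voxel coords)
chain_path <- function(g, ch) {
  if (length(ch) == 1) return(g$edges[[ch]]$path)
  paths <- lapply(ch, function(ei) g$edges[[ei]]$path)
  out <- paths[[1]]
  for (k in 2:length(paths)) {
    p <- paths[[k]]
    tail_pt <- out[nrow(out), ]
    d_head <- sum((p[1, ] - tail_pt)^2)
    d_tail <- sum((p[nrow(p), ] - tail_pt)^2)
    if (d_tail < d_head) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    if (sum((p[1, ] - tail_pt)^2) > sum((p[1, ] - out[1, ])^2)) {
      out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
      tail_pt <- out[nrow(out), ]
      if (sum((p[nrow(p), ] - tail_pt)^2) < sum((p[1, ] - tail_pt)^2))
        p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    out <- rbind(out, p[-1, , drop = FALSE])
  }
  out
}

# per-path binned axis profile: mean (z, x) per integer y bin
prox_profile <- function(path) {
  b <- round(path[, 2])
  s <- rowsum(cbind(path[, 1], path[, 3], 1), b)
  list(bins = as.integer(rownames(s)), z = s[, 1] / s[, 3],
       x = s[, 2] / s[, 3])
}

# mean separation of two skeleton paths over their common span along the
# dominant (y) axis: returns overlap fraction (of the shorter path) and
# mean |dz|, |dx| in voxels, or NULL if they do not overlap
path_proximity <- function(p1, p2) {
  pr1 <- if (is.list(p1) && !is.null(p1$bins)) p1 else prox_profile(p1)
  pr2 <- if (is.list(p2) && !is.null(p2$bins)) p2 else prox_profile(p2)
  m <- match(pr1$bins, pr2$bins)
  ok <- !is.na(m)
  if (!any(ok)) return(NULL)
  c(overlap = sum(ok) / min(length(pr1$bins), length(pr2$bins)),
    dz = mean(abs(pr1$z[ok] - pr2$z[m[ok]])),
    dx = mean(abs(pr1$x[ok] - pr2$x[m[ok]])))
}

# connected components (lists of edge indices) of a residual edge subset,
# connected through shared nodes
residual_components <- function(g, res) {
  nn <- nrow(g$nodes)
  parent <- seq_len(nn)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (ei in res) {
    a <- find(g$edges[[ei]]$n1); b <- find(g$edges[[ei]]$n2)
    if (a != b) parent[a] <- b
  }
  roots <- vapply(res, function(ei) find(g$edges[[ei]]$n1), integer(1))
  split(res, roots)
}

# shortest path (by edge length) within a residual component between any
# node of `from` and any node of `to`; returns edge list and total length
residual_shortest_path <- function(g, cmp, from, to) {
  nds <- unique(unlist(lapply(cmp, function(ei)
    c(g$edges[[ei]]$n1, g$edges[[ei]]$n2))))
  idx <- match(nds, nds)
  dist <- rep(Inf, length(nds))
  prev_edge <- rep(NA_integer_, length(nds))
  prev_node <- rep(NA_integer_, length(nds))
  dist[match(intersect(from, nds), nds)] <- 0
  done <- rep(FALSE, length(nds))
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (ei in cmp) {
      e <- g$edges[[ei]]
      a <- match(e$n1, nds); b <- match(e$n2, nds)
      for (pr in list(c(a, b), c(b, a))) {
        if (pr[1] == u && !done[pr[2]] &&
            dist[u] + e$length_nm < dist[pr[2]]) {
          dist[pr[2]] <- dist[u] + e$length_nm
          prev_edge[pr[2]] <- ei
          prev_node[pr[2]] <- u
        }
      }
    }
  }
  tm <- match(intersect(to, nds), nds)
  tm <- tm[is.finite(dist[tm])]
  if (!length(tm)) return(NULL)
  tgt <- tm[which.min(dist[tm])]
  edges <- integer(0)
  cur <- tgt
  while (!is.na(prev_edge[cur])) {
    edges <- c(prev_edge[cur], edges)
    cur <- prev_node[cur]
  }
  list(edges = edges, len = dist[tgt], from = nds[cur], to = nds[tgt])
}

# local centerline position of a fibril nearest to a point (voxel coords)
fibril_point_near <- function(fib, pt) {
  d2 <- rowSums(sweep(fib$path, 2, pt)^2)
  k <- which.min(d2)
  iw <- max(1, k - 2):min(nrow(fib$path), k + 2)
  colMeans(fib$path[iw, , drop = FALSE])
}

# median radius of a fibril near a point (voxel coords), excluding the
# junction voxel itself whose EDT is inflated by the attached bridge
fibril_radius_near <- function(fib, pt, vs) {
  pt <- as.numeric(pt)
  d2 <- rowSums(sweep(fib$path, 2, pt)^2)
  sel <- which(d2 > 0.5 & d2 <= 16)   # within 4 voxels, not the junction
  if (!length(sel)) sel <- order(d2)[seq_len(min(3, length(d2)))]
  stats::median(fib$radii_nm[sel])
}
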