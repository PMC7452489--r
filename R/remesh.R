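# Isotropic remeshing to a target edge length.
#
# Classic incremental loop: split edges longer than 4/3 of the target,
# collapse edges shorter than 4/5 of the target, flip edges towards
# regular vertex valence, then relax vertices tangentially. Edge lengths
# land within about 50% of the target; the surface itself moves very
# little because vertices are only ever inserted on the surface or moved
# within their local tangent plane.

#' Remesh a surface to an approximately uniform edge length
#'
#' @param mesh a [trimesh()]
#' @param target_edge target edge length, mm; lengths 2-4 mm are the
#'   intended working range for a patella — values outside it warn
#' @param iterations outer split/collapse/flip/smooth iterations
#' @return a remeshed [trimesh()]
#' @export
remesh_uniform <- function(mesh, target_edge, iterations = 5) {
  if (nrow(mesh$faces) == 0) stop("cannot remesh an empty mesh")
  stopifnot_finite(target_edge, "target_edge")
  if (target_edge <= 0) stop("target_edge must be positive")
  if (target_edge < 2 || target_edge > 4) {
    warning(sprintf(
      "target_edge %.2f mm is outside the intended 2-4 mm range", target_edge))
  }
  V <- mesh$vertices
  F_ <- mesh$faces
  hi <- 4 / 3 * target_edge
  lo <- 4 / 5 * target_edge
  for (it in seq_len(iterations)) {
    sp <- split_long_edges(V, F_, hi)
    V <- sp$V; F_ <- sp$F
    co <- collapse_short_edges(V, F_, lo, hi)
    V <- co$V; F_ <- co$F
    fl <- flip_for_valence(V, F_)
    F_ <- fl$F
    V <- tangential_smooth(V, F_, lambda = 0.5)
  }
  clean_mesh(trimesh(V, F_))
}

# --- split ------------------------------------------------------------------

split_long_edges <- function(V, F_, maxlen, max_rounds = 12) {
  for (round in seq_len(max_rounds)) {
    m <- trimesh(V, F_)
    ed <- mesh_edges(m)
    len <- edge_lengths(m, ed)
    long <- which(len > maxlen)
    if (length(long) == 0) break
    # greedy matching: at most one split per face per round
    long <- long[order(len[long], decreasing = TRUE)]
    face_used <- logical(nrow(F_))
    chosen <- integer(0)
    for (e in long) {
      fs <- c(ed$f1[e], ed$f2[e]); fs <- fs[!is.na(fs)]
      if (any(face_used[fs])) next
      face_used[fs] <- TRUE
      chosen <- c(chosen, e)
    }
    if (length(chosen) == 0) break
    mids <- (V[ed$v1[chosen], , drop = FALSE] + V[ed$v2[chosen], , drop = FALSE]) / 2
    mid_idx <- nrow(V) + seq_along(chosen)
    V <- rbind(V, mids)
    new_faces <- list()
    drop_faces <- integer(0)
    for (k in seq_along(chosen)) {
      e <- chosen[k]
      a <- ed$v1[e]; b <- ed$v2[e]; mid <- mid_idx[k]
      for (f in c(ed$f1[e], ed$f2[e])) {
        if (is.na(f)) next
        tri <- F_[f, ]
        # locate the edge in cyclic order u -> v, w opposite
        if (setequal(tri[c(1, 2)], c(a, b))) { u <- tri[1]; v <- tri[2]; w <- tri[3] }
        else if (setequal(tri[c(2, 3)], c(a, b))) { u <- tri[2]; v <- tri[3]; w <- tri[1] }
        else { u <- tri[3]; v <- tri[1]; w <- tri[2] }
        new_faces <- c(new_faces, list(c(u, mid, w), c(mid, v, w)))
        drop_faces <- c(drop_faces, f)
      }
    }
    new_faces <- new_faces[!vapply(new_faces, is.null, logical(1))]
    F_ <- rbind(F_[-drop_faces, , drop = FALSE],
                do.call(rbind, new_faces))
  }
  list(V = V, F = F_)
}

# --- collapse ---------------------------------------------------------------

vertex_neighbors <- function(edges, nv) {
  nb <- vector("list", nv)
  both <- c(edges$v1, edges$v2)
  other <- c(edges$v2, edges$v1)
  sp <- split(other, both)
  nb[as.integer(names(sp))] <- sp
  nb
}

collapse_short_edges <- function(V, F_, minlen, maxlen, passes = 3) {
  for (pass in seq_len(passes)) {
    m <- trimesh(V, F_)
    ed <- mesh_edges(m)
    len <- edge_lengths(m, ed)
    short <- which(len < minlen)
    if (length(short) == 0) break
    short <- short[order(len[short])]
    boundary_v <- unique(c(ed$v1[is.na(ed$f2)], ed$v2[is.na(ed$f2)]))
    on_boundary <- logical(nrow(V)); on_boundary[boundary_v] <- TRUE
    nb <- vertex_neighbors(ed, nrow(V))
    touched <- logical(nrow(V))
    dead_face <- logical(nrow(F_))
    remap <- seq_len(nrow(V))
    did <- 0L
    for (e in short) {
      a <- ed$v1[e]; b <- ed$v2[e]
      if (touched[a] || touched[b]) next
      if (on_boundary[a] || on_boundary[b]) next
      na_ <- nb[[a]]; nb_ <- nb[[b]]
      common <- intersect(na_, nb_)
      # link condition: shared neighbors must be exactly the two apex
      # vertices of the faces flanking edge (a, b)
      if (length(common) != 2) next
      mid <- (V[a, ] + V[b, ]) / 2
      ring <- setdiff(union(na_, nb_), c(a, b))
      d <- sweep(V[ring, , drop = FALSE], 2, mid)
      if (any(sqrt(rowSums(d * d)) > maxlen)) next
      # normal-flip guard on surviving incident faces
      inc <- which(rowSums(matrix(F_ %in% c(a, b), ncol = 3)) == 1 & !dead_face)
      if (length(inc)) {
        tri_old <- F_[inc, , drop = FALSE]
        n_old <- tri_normals(V, tri_old)
        V_try <- V; V_try[a, ] <- mid; V_try[b, ] <- mid
        n_new <- tri_normals(V_try, tri_old)
        if (any(rowSums(n_old * n_new) < 0.2)) next
      }
      # commit
      V[a, ] <- mid
      remap[b] <- a
      dead <- which(rowSums(matrix(F_ == a, ncol = 3) | matrix(F_ == b, ncol = 3)) >= 2)
      dead_face[dead] <- TRUE
      touched[c(a, b, ring)] <- TRUE
      did <- did + 1L
    }
    if (did == 0L) break
    F_ <- matrix(remap[F_], ncol = 3)
    F_ <- F_[!dead_face & !(F_[, 1] == F_[, 2] | F_[, 2] == F_[, 3] | F_[, 1] == F_[, 3]), ,
             drop = FALSE]
    keep <- clean_mesh(trimesh(V, F_))
    V <- keep$vertices; F_ <- keep$faces
  }
  list(V = V, F = F_)
}

tri_normals <- function(V, tri) {
  a <- V[tri[, 1], , drop = FALSE]
  n <- cross3(V[tri[, 2], , drop = FALSE] - a, V[tri[, 3], , drop = FALSE] - a)
  nn <- row_norms(n)
  n / pmax(nn, 1e-12)
}

# --- flips ------------------------------------------------------------------

flip_for_valence <- function(V, F_) {
  m <- trimesh(V, F_)
  ed <- mesh_edges(m)
  val <- tabulate(c(ed$v1, ed$v2), nbins = nrow(V))
  boundary_v <- unique(c(ed$v1[is.na(ed$f2)], ed$v2[is.na(ed$f2)]))
  target <- rep(6L, nrow(V)); target[boundary_v] <- 4L
  edge_key <- paste(ed$v1, ed$v2)
  has_edge <- new.env(hash = TRUE)
  for (k in edge_key) assign(k, TRUE, envir = has_edge)
  face_used <- logical(nrow(F_))
  interior <- which(!is.na(ed$f2))
  for (e in interior) {
    f1 <- ed$f1[e]; f2 <- ed$f2[e]
    if (face_used[f1] || face_used[f2]) next
    a <- ed$v1[e]; b <- ed$v2[e]
    c1 <- setdiff(F_[f1, ], c(a, b))
    c2 <- setdiff(F_[f2, ], c(a, b))
    if (length(c1) != 1 || length(c2) != 1 || c1 == c2) next
    kk <- paste(min(c1, c2), max(c1, c2))
    if (!is.null(has_edge[[kk]])) next
    dev_before <- sum((val[c(a, b, c1, c2)] - target[c(a, b, c1, c2)])^2)
    val2 <- val; val2[c(a, b)] <- val2[c(a, b)] - 1L; val2[c(c1, c2)] <- val2[c(c1, c2)] + 1L
    dev_after <- sum((val2[c(a, b, c1, c2)] - target[c(a, b, c1, c2)])^2)
    if (dev_after >= dev_before) next
    # orientation-preserving rebuild of the two faces around diagonal c1-c2
    t1 <- F_[f1, ]
    # order (u, v) as the cyclic a-b direction in f1
    if ((which(t1 == a) %% 3) + 1 == which(t1 == b)) { u <- a; v <- b } else { u <- b; v <- a }
    newf1 <- c(u, c2, c1)
    newf2 <- c(c2, v, c1)
    n_old <- tri_normals(V, rbind(F_[f1, ], F_[f2, ]))
    n_new <- tri_normals(V, rbind(newf1, newf2))
    ar <- face_areas(trimesh(V, rbind(newf1, newf2)))
    n_ref <- colMeans(n_old)
    if (any(ar < 1e-8) || any(as.numeric(n_new %*% n_ref) < 0.2)) next
    F_[f1, ] <- newf1
    F_[f2, ] <- newf2
    val <- val2
    face_used[c(f1, f2)] <- TRUE
    assign(kk, TRUE, envir = has_edge)
  }
  list(F = F_)
}

# --- smoothing --------------------------------------------------------------

tangential_smooth <- function(V, F_, lambda = 0.5) {
  m <- trimesh(V, F_)
  ed <- mesh_edges(m)
  boundary_v <- unique(c(ed$v1[is.na(ed$f2)], ed$v2[is.na(ed$f2)]))
  nb <- vertex_neighbors(ed, nrow(V))
  # area-weighted vertex normals
  av <- face_area_vectors(m)
  vn <- rowsum_accumulate(av, F_, nrow(V))
  vn <- vn / pmax(row_norms(vn), 1e-12)
  out <- V
  for (i in seq_len(nrow(V))) {
    if (i %in% boundary_v) next
    ni <- nb[[i]]
    if (length(ni) < 3) next
    g <- colMeans(V[ni, , drop = FALSE])
    d <- g - V[i, ]
    d <- d - sum(d * vn[i, ]) * vn[i, ]
    out[i, ] <- V[i, ] + lambda * d
  }
  out
}

# Sum face area vectors onto their three corner vertices.
rowsum_accumulate <- function(av, F_, nv) {
  idx <- c(F_[, 1], F_[, 2], F_[, 3])
  vals <- rbind(av, av, av)
  acc <- rowsum(vals, group = idx)
  out <- matrix(0, nv, 3)
  out[as.integer(rownames(acc)), ] <- acc
  out
}
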