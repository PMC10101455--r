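#' Rigid-body transform
#'
#' A 6-DOF world-space map: rotation (Euler angles, degrees, applied in
#' x-y-z order about `center`) followed by translation in mm.
#'
#' @param rotation length-3 numeric, degrees about the world x, y, z axes
#' @param translation length-3 numeric, mm
#' @param center rotation center in world mm (default origin); registration
#'   parameterizes rotations about the image center for conditioning
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' General affine world-to-world transform
#' @param matrix 4x4 matrix with last row (0, 0, 0, 1); must be invertible
#' @return object of class `affine_transform`
#' @export
affine_transform <- function(matrix) {
  if (!is.matrix(matrix) || any(dim(matrix) != c(4, 4)))
    stop("affine transform needs a 4x4 matrix")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row must be (0, 0, 0, 1)")
  if (!is.finite(kappa(matrix))) stop("transform matrix is not invertible")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @rdname transform_matrix
#' @export
transform_matrix <- function(x, ...) UseMethod("transform_matrix")

#' 4x4 matrix of a transform
#'
#' Rigid transforms compose as T(center) R T(-center) then translation;
#' rotations are right-handed about the world axes, applied Rz Ry Rx.
#' @param x a `rigid_transform` or `affine_transform`
#' @param ... unused
#' @return 4x4 matrix
#' @export
transform_matrix.rigid_transform <- function(x, ...) {
  th <- x$rotation * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- x$translation + x$center - R %*% x$center
  m
}

#' @rdname transform_matrix
#' @export
transform_matrix.affine_transform <- function(x, ...) x$matrix

#' Invert a transform
#' @param x a transform
#' @return transform of the same class mapping in the opposite direction
#' @export
invert_transform <- function(x) {
  if (inherits(x, "rigid_transform")) {
    m <- solve(transform_matrix(x))
    rigid_from_matrix(m, center = x$center)
  } else {
    affine_transform(solve(transform_matrix(x)))
  }
}

# Recover Euler angles/translation from a rigid 4x4 (Rz Ry Rx convention).
rigid_from_matrix <- function(m, center = c(0, 0, 0)) {
  R <- m[1:3, 1:3]
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  rot <- c(rx, ry, rz) * 180 / pi
  tr <- m[1:3, 4] - (center - R %*% center)
  rigid_transform(rot, as.numeric(tr), center)
}

#' Compose transforms into a single affine map
#'
#' `compose_transforms(a, b)` returns the map "apply a, then b" — i.e. the
#' matrix product B A. Composition into one matrix means downstream
#' resampling interpolates exactly once however long the chain is.
#' @param ... transforms, in application order
#' @return an `affine_transform`
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  if (length(ts) == 1 && is.list(ts[[1]]) && !inherits(ts[[1]], c("rigid_transform", "affine_transform")))
    ts <- ts[[1]]
  m <- diag(4)
  for (t in ts) m <- transform_matrix(t) %*% m
  affine_transform(m)
}

#' Transform chain with space bookkeeping
#'
#' An ordered list of transforms, each tagged with the space it maps from
#' and to (e.g. "MNI" -> "T1" -> "NM"). Adjacent labels must match; the
#' chain composes to one affine so ROI mapping interpolates once.
#' @param transforms list of `rigid_transform`/`affine_transform`
#' @param spaces character vector of length `length(transforms) + 1` naming
#'   the spaces along the chain
#' @return object of class `transform_chain`
#' @export
transform_chain <- function(transforms, spaces) {
  if (length(spaces) != length(transforms) + 1)
    stop("need one space label more than transforms")
  structure(list(transforms = transforms, spaces = spaces),
            class = "transform_chain")
}

#' @export
transform_matrix.transform_chain <- function(x, ...) {
  transform_matrix(compose_transforms(x$transforms))
}

chain_connects <- function(chain, from, to) {
  n <- length(chain$spaces)
  identical(chain$spaces[1], from) && identical(chain$spaces[n], to)
}

#' Serialize / deserialize transforms as JSON
#'
#' Rigid transforms store their 6 parameters (+ center); affines the 16
#' matrix entries; chains their space labels.
#' @param x transform or `transform_chain`
#' @param path JSON file path
#' @return `read_transform` returns the deserialized object
#' @export
write_transform <- function(x, path) {
  enc <- function(t) {
    if (inherits(t, "rigid_transform"))
      list(type = "rigid", rotation = t$rotation,
           translation = t$translation, center = t$center)
    else list(type = "affine", matrix = as.vector(t$matrix))
  }
  obj <- if (inherits(x, "transform_chain"))
    list(type = "chain", spaces = x$spaces,
         transforms = lapply(x$transforms, enc))
  else enc(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(o) {
    if (o$type == "rigid")
      rigid_transform(o$rotation, o$translation, o$center)
    else affine_transform(matrix(o$matrix, 4, 4))
  }
  if (identical(obj$type, "chain")) {
    ts <- lapply(seq_len(nrow_or_len(obj$transforms)), function(i)
      dec(pick_row(obj$transforms, i)))
    transform_chain(ts, obj$spaces)
  } else dec(obj)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_row <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col) {
    v <- if (is.list(col)) col[[i]] else col[i]
    unlist(v)
  })
  else x[[i]]
}

#' Resample an image, atlas or mask onto a target grid
#'
#' Applies a world-space transform (source world -> target world) and pulls
#' source intensities onto the target grid in a single interpolation pass:
#' trilinear for intensities and probabilities, nearest-neighbour for masks.
#' Out-of-field voxels fill with 0 (FALSE for masks).
#'
#' @param source `voxel_image`, `prob_atlas` or `binary_mask`
#' @param transform a transform, `transform_chain`, or list of transforms
#'   applied in order; mapped source world coords -> target world coords
#' @param target a `voxel_image` (or compatible) defining the output grid
#' @return same class as `source`, on `target`'s grid
#' @export
resample <- function(source, transform, target) {
  m <- if (is.list(transform) &&
           !inherits(transform, c("rigid_transform", "affine_transform",
                                  "transform_chain")))
    transform_matrix(compose_transforms(transform))
  else transform_matrix(transform)
  if (!is.finite(kappa(m))) stop("non-invertible transform")
  # target voxel -> target world -> source world -> source voxel
  map <- solve(source$affine) %*% solve(m) %*% target$affine
  d <- dim(target$data)
  cont <- voxel_grid_map(map, d)   # n x 3 continuous 0-based source coords
  sd <- dim(source$data)
  if (inherits(source, "binary_mask")) {
    idx <- round(cont)
    ok <- idx[, 1] >= 0 & idx[, 1] <= sd[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= sd[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= sd[3] - 1
    out <- logical(nrow(idx))
    lin <- 1 + idx[ok, 1] + sd[1] * (idx[ok, 2] + sd[2] * idx[ok, 3])
    out[ok] <- source$data[lin]
    binary_mask(array(out, dim = d), target$affine)
  } else {
    vals <- trilinear_sample(source$data, cont)
    if (inherits(source, "prob_atlas"))
      prob_atlas(array(pmin(1, pmax(0, vals)), dim = d), target$affine)
    else voxel_image(array(vals, dim = d), target$affine)
  }
}

# All target voxel centers (0-based), mapped through a 4x4 into source
# voxel coordinates. Returns an n x 3 matrix, n = prod(shape).
voxel_grid_map <- function(map, shape) {
  i <- rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3])
  j <- rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3])
  k <- rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  x <- map[1, 1] * i + map[1, 2] * j + map[1, 3] * k + map[1, 4]
  y <- map[2, 1] * i + map[2, 2] * j + map[2, 3] * k + map[2, 4]
  z <- map[3, 1] * i + map[3, 2] * j + map[3, 3] * k + map[3, 4]
  cbind(x, y, z, deparse.level = 0)
}

# Vectorized trilinear interpolation at continuous 0-based voxel coords;
# contributions from corners outside the array are 0.
trilinear_sample <- function(arr, cont) {
  sd <- dim(arr)
  f0 <- floor(cont)
  fr <- cont - f0
  n <- nrow(cont)
  acc <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- f0[, 1] + dx; cj <- f0[, 2] + dy; ck <- f0[, 3] + dz
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ok <- ci >= 0 & ci <= sd[1] - 1 & cj >= 0 & cj <= sd[2] - 1 &
          ck >= 0 & ck <= sd[3] - 1 & w > 0
    if (any(ok)) {
      lin <- 1 + ci[ok] + sd[1] * (cj[ok] + sd[2] * ck[ok])
      acc[ok] <- acc[ok] + w[ok] * arr[lin]
    }
  }
  acc
}
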