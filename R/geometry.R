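#' Jaw landmark geometry
#'
#' Holds the 3D landmark set of one hemi-jaw in a fixed skull frame:
#' the centre of the condylar process (the rotation centre of the mandible),
#' per-muscle cranial origin centroids, per-muscle mandibular insertion
#' centroids, and one or more bite points (tooth positions at which the
#' output force is evaluated).
#'
#' Coordinate frame convention: x = anteroposterior (+ anterior),
#' y = dorsoventral (+ dorsal), z = mediolateral. The sagittal plane is x-y;
#' jaw rotation happens about the mediolateral axis through the condyle.
#' All coordinates in millimetres.
#'
#' @param condyle Numeric length-3 point, mm.
#' @param origins Numeric matrix (n x 3) with muscle labels as row names.
#' @param insertions Numeric matrix (n x 3), same row names as `origins`.
#' @param bite_points Numeric matrix (m x 3) with bite labels as row names
#'   (conventionally `"incisor"` and `"m4"`).
#' @param gape Current opening angle in degrees (0 = closed).
#'
#' @return An object of class `jaw_geometry`.
#' @seealso [action_line()], [rotate_mandible()], [bite_distance()],
#'   [generate_geometry()]
#' @export
jaw_geometry <- function(condyle, origins, insertions, bite_points,
                         gape = 0) {
  condyle <- as_point3(condyle, "condyle")
  origins <- as_pointmat(origins, "origins")
  insertions <- as_pointmat(insertions, "insertions")
  bite_points <- as_pointmat(bite_points, "bite_points")
  if (!setequal(rownames(origins), rownames(insertions)))
    stop("origins and insertions must cover the same muscles", call. = FALSE)
  insertions <- insertions[rownames(origins), , drop = FALSE]
  if (!is.numeric(gape) || length(gape) != 1L || !is.finite(gape) || gape < 0)
    stop("gape must be a single non-negative angle in degrees", call. = FALSE)
  degen <- rownames(origins)[rowSums((origins - insertions)^2) == 0]
  if (length(degen))
    stop("origin coincides with insertion for muscle(s): ",
         paste(degen, collapse = ", "), call. = FALSE)
  coincident <- rownames(bite_points)[
    colSums((t(bite_points) - condyle)^2) == 0]
  if (length(coincident))
    stop("bite point(s) coincide with the condyle: ",
         paste(coincident, collapse = ", "), call. = FALSE)
  structure(list(condyle = condyle, origins = origins,
                 insertions = insertions, bite_points = bite_points,
                 gape = gape),
            class = "jaw_geometry")
}

as_point3 <- function(p, what) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("'", what, "' must be a finite 3D point", call. = FALSE)
  p
}

as_pointmat <- function(m, what) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L || is.null(rownames(m)) || any(!is.finite(m)))
    stop("'", what, "' must be a labelled n x 3 matrix of finite coordinates",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate labels in '", what, "'", call. = FALSE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.jaw_geometry <- function(x, ...) {
  cat("Jaw geometry:", nrow(x$origins), "muscles,",
      nrow(x$bite_points), "bite points, gape",
      format(x$gape), "deg\n")
  cat("  condyle at (", paste(format(round(x$condyle, 3)), collapse = ", "),
      ") mm\n", sep = "")
  cat("  muscles:", paste(rownames(x$origins), collapse = ", "), "\n")
  cat("  bite points:", paste(rownames(x$bite_points), collapse = ", "), "\n")
  invisible(x)
}

#' Read a landmark CSV into a jaw geometry
#'
#' Expects columns `landmark,role,x_mm,y_mm,z_mm`, where `role` is one of
#' `condyle`, `origin:<muscle>`, `insertion:<muscle>`, `bite:<label>`.
#' A JSON file with top-level `condyle`, `origins`, `insertions`,
#' `bite_points` objects (label -> [x, y, z]) is accepted as well.
#'
#' @param path Path to the CSV or JSON file.
#' @return A `jaw_geometry` object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("landmark file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    tomat <- function(x) {
      if (is.data.frame(x)) x <- as.matrix(x)
      if (is.list(x)) x <- do.call(rbind, x)
      x
    }
    return(jaw_geometry(unlist(j$condyle), tomat(j$origins),
                        tomat(j$insertions), tomat(j$bite_points)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("landmark", "role", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("landmark file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  xyz <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  pick <- function(prefix) {
    sel <- startsWith(df$role, prefix)
    m <- xyz[sel, , drop = FALSE]
    rownames(m) <- sub(prefix, "", df$role[sel], fixed = TRUE)
    m
  }
  ic <- which(df$role == "condyle")
  if (length(ic) != 1L)
    stop("landmark file must contain exactly one 'condyle' row", call. = FALSE)
  jaw_geometry(xyz[ic, ], pick("origin:"), pick("insertion:"), pick("bite:"))
}

#' Derive a muscle's line of action from landmarks
#'
#' The action vector points from the mandibular insertion toward the cranial
#' origin (the direction the muscle pulls the jaw). From it are derived:
#' `phi`, the angle between the 3D action vector and the mediolateral axis
#' (so `sin(phi)` is the sagittal fraction of the force); `theta`, the angle
#' in the sagittal plane between the in-lever vector condyle -> insertion
#' and the sagittal projection of the action vector; `lever`, the
#' sagittal-plane condyle-insertion distance (the in-lever); and
#' `moment_sign`, -1 for a jaw-closing moment and +1 for an opening one
#' (0 when the action line passes through the condyle).
#'
#' @param geom A [jaw_geometry()].
#' @param muscle Muscle label present in the geometry.
#' @return A one-row `data.frame` with columns `muscle`, `phi`, `theta`,
#'   `lever`, `moment_sign` (angles in degrees, lever in mm).
#' @export
action_line <- function(geom, muscle) {
  stopifnot(inherits(geom, "jaw_geometry"))
  if (!muscle %in% rownames(geom$origins))
    stop("unknown muscle: ", muscle, call. = FALSE)
  ins <- geom$insertions[muscle, ]
  ori <- geom$origins[muscle, ]
  v <- ori - ins                      # pull direction, insertion -> origin
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop("degenerate geometry: zero-length action vector for muscle ",
         muscle, call. = FALSE)
  phi <- rad2deg(acos(max(-1, min(1, v[3] / nv))))
  v2 <- v[1:2]
  n2 <- sqrt(sum(v2^2))
  if (n2 == 0)
    stop("degenerate geometry: action line of muscle ", muscle,
         " is purely mediolateral (no sagittal projection)", call. = FALSE)
  l <- (ins - geom$condyle)[1:2]      # in-lever vector, sagittal plane
  nl <- sqrt(sum(l^2))
  if (nl == 0)
    stop("degenerate geometry: insertion of muscle ", muscle,
         " coincides with the condyle in the sagittal plane", call. = FALSE)
  cth <- sum(l * v2) / (nl * n2)
  theta <- rad2deg(acos(max(-1, min(1, cth))))
  ## z-moment of the sagittal force about the condyle; with +x anterior and
  ## +y dorsal, opening rotates points clockwise in x-y, so a right-handed
  ## positive z-moment closes the jaw.  Sign convention: closing < 0.
  mz <- l[1] * v2[2] - l[2] * v2[1]
  data.frame(muscle = muscle, phi = phi, theta = theta, lever = nl,
             moment_sign = -sign(mz), stringsAsFactors = FALSE)
}

#' Action lines for every muscle of a geometry
#'
#' @inheritParams action_line
#' @return A `data.frame`, one row per muscle, as in [action_line()].
#' @export
action_lines <- function(geom) {
  stopifnot(inherits(geom, "jaw_geometry"))
  out <- do.call(rbind, lapply(rownames(geom$origins),
                               function(m) action_line(geom, m)))
  rownames(out) <- NULL
  out
}

#' Rigidly rotate the mandible about the condyle
#'
#' Rotates every mandibular point (insertion centroids and bite points) by
#' `delta` degrees about the mediolateral axis through the condyle, in the
#' opening sense for positive `delta` (the tooth row swings ventrally).
#' Cranial points (origins) and the condyle itself are unchanged; `gape` is
#' incremented by `delta`. Mediolateral (z) coordinates are untouched.
#'
#' @param geom A [jaw_geometry()].
#' @param delta Rotation increment, degrees. Negative values close the jaw.
#' @return A new `jaw_geometry` at the new gape.
#' @export
rotate_mandible <- function(geom, delta) {
  stopifnot(inherits(geom, "jaw_geometry"))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("'delta' must be a single finite angle in degrees", call. = FALSE)
  d <- deg2rad(delta)
  ## opening = clockwise in the (x anterior, y dorsal) plane
  rot <- function(m) {
    dx <- m[, 1] - geom$condyle[1]
    dy <- m[, 2] - geom$condyle[2]
    m[, 1] <- geom$condyle[1] + cos(d) * dx + sin(d) * dy
    m[, 2] <- geom$condyle[2] - sin(d) * dx + cos(d) * dy
    m
  }
  out <- geom
  out$insertions <- rot(geom$insertions)
  out$bite_points <- rot(geom$bite_points)
  out$gape <- geom$gape + delta
  out
}

#' Out-lever: sagittal distance from condyle to a bite point
#'
#' @inheritParams action_line
#' @param bite Bite-point label.
#' @return Distance in mm (strictly positive).
#' @export
bite_distance <- function(geom, bite) {
  stopifnot(inherits(geom, "jaw_geometry"))
  if (!bite %in% rownames(geom$bite_points))
    stop("unknown bite point: ", bite, call. = FALSE)
  d <- (geom$bite_points[bite, ] - geom$condyle)[1:2]
  out <- sqrt(sum(d^2))
  if (out == 0)
    stop("bite point ", bite,
         " coincides with the condyle in the sagittal plane", call. = FALSE)
  out
}
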