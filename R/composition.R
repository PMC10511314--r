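#' Canonical 24-h movement behaviors
#'
#' The four mutually exclusive, exhaustive daily activities in their canonical
#' order: sleep, sedentary behavior (SED), light physical activity (LPA) and
#' moderate-to-vigorous physical activity (MVPA). Together they always account
#' for the full 1440-minute day, which is what makes daily time use
#' compositional: only the relative information in the four parts is
#' meaningful.
#'
#' @return Character vector `c("sleep", "sed", "lpa", "mvpa")`.
#' @export
behaviors <- function() c("sleep", "sed", "lpa", "mvpa")

#' Construct a 4-part daily time-use composition
#'
#' Closes a vector of strictly positive behavior times (or shares) to the unit
#' simplex and tags it with the day length used to convert back to minutes.
#' Parts are stored in the canonical order of [behaviors()]; named input is
#' reordered, unnamed input is assumed already canonical.
#'
#' @param x Numeric vector of 4 strictly positive parts (minutes/day or any
#'   positive multiples of the shares), optionally named with behavior names.
#' @param day_minutes Scale constant for the minutes view (default 1440).
#' @return A `composition`: named proportions summing to 1 with a
#'   `day_minutes` attribute.
#' @examples
#' composition(c(sleep = 497, sed = 584, lpa = 282, mvpa = 77))
#' @export
composition <- function(x, day_minutes = 1440) {
  x <- canonical_parts(x)
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop("composition parts must be strictly positive; offending behavior(s): ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  }
  out <- x / sum(x)
  attr(out, "day_minutes") <- day_minutes
  class(out) <- "composition"
  out
}

# Coerce to a named length-4 vector in canonical order.
canonical_parts <- function(x) {
  b <- behaviors()
  if (length(x) != 4L) stop("a composition has exactly 4 parts", call. = FALSE)
  x <- as.numeric_keep_names(x)
  if (!is.null(names(x)) && !all(names(x) == "")) {
    names(x) <- normalize_behavior_names(names(x))
    if (!setequal(names(x), b)) {
      stop("part names must be exactly {", paste(b, collapse = ", "), "}",
           call. = FALSE)
    }
    x <- x[b]
  } else {
    names(x) <- b
  }
  x
}

# Map column/part labels like "sleep_min_pre" onto the behavior names.
normalize_behavior_names <- function(nm) {
  sub("_.*$", "", tolower(nm))
}

as.numeric_keep_names <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' @export
print.composition <- function(x, ...) {
  cat("4-part time-use composition (proportions):\n")
  print(round(unclass(x), 5))
  cat("minutes/day:\n")
  print(round(as_minutes(x), 1))
  invisible(x)
}

#' Closure: rescale positive parts to the unit simplex
#'
#' @param x Positive numeric vector (or `composition`).
#' @param day_minutes Day length attached to the result.
#' @return A `composition`.
#' @export
closure <- function(x, day_minutes = 1440) {
  if (inherits(x, "composition")) return(x)
  composition(x, day_minutes = day_minutes)
}

#' Minutes/day view of a composition
#'
#' @param x A `composition`.
#' @return Named numeric vector of minutes summing to `day_minutes`.
#' @export
as_minutes <- function(x) {
  stopifnot(inherits(x, "composition"))
  p <- unclass(x)
  v <- p * attr(p, "day_minutes")
  attributes(v) <- list(names = names(p))
  v
}

#' Perturbation: the simplex group operation
#'
#' Element-wise product followed by closure; the compositional analogue of
#' addition. `comp_diff()` is its inverse: the element-wise ratio
#' `post / pre`, closed, so that `comp_perturb(pre, comp_diff(post, pre))`
#' recovers `post`.
#'
#' @param x,y `composition` objects (or positive 4-vectors).
#' @return A `composition`.
#' @export
comp_perturb <- function(x, y) {
  x <- closure(x); y <- closure(y)
  composition(unclass(x) * unclass(y), day_minutes = attr(x, "day_minutes"))
}

#' Compositional difference between two waves
#'
#' The per-participant change in the behavior composition: the perturbation
#' difference `post` minus `pre` in the Aitchison geometry. An unchanged
#' composition maps to the neutral element (1/4, 1/4, 1/4, 1/4).
#'
#' @param post,pre `composition` objects (or positive 4-vectors).
#' @rdname comp_perturb
#' @export
comp_diff <- function(post, pre) {
  post <- closure(post); pre <- closure(pre)
  composition(unclass(post) / unclass(pre),
              day_minutes = attr(post, "day_minutes"))
}

#' Compositional mean of a sample
#'
#' Closure of the part-wise geometric means -- the center of a compositional
#' sample, identical to the inverse ilr of the arithmetic mean of the ilr
#' coordinates.
#'
#' @param x A list of `composition`s, or a numeric matrix with one composition
#'   per row (columns in canonical order or named).
#' @param day_minutes Day length attached to the result.
#' @return A `composition`.
#' @export
comp_mean <- function(x, day_minutes = 1440) {
  m <- comp_matrix(x)
  if (nrow(m) == 0L) stop("cannot take the compositional mean of an empty sample",
                          call. = FALSE)
  composition(exp(colMeans(log(m))), day_minutes = day_minutes)
}

# Stack compositions / rows into an n x 4 positive matrix in canonical order.
comp_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) stop("empty compositional sample", call. = FALSE)
    m <- do.call(rbind, lapply(x, function(z) unclass(closure(z))))
  } else if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    if (!is.null(colnames(m))) {
      colnames(m) <- normalize_behavior_names(colnames(m))
      if (!setequal(colnames(m), behaviors())) {
        stop("columns must map onto the behaviors {",
             paste(behaviors(), collapse = ", "), "}", call. = FALSE)
      }
      m <- m[, behaviors(), drop = FALSE]
    }
  } else {
    m <- matrix(unclass(closure(x)), nrow = 1L)
  }
  if (is.null(m) || ncol(m) != 4L) {
    stop("expected 4 parts per composition", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("all composition parts must be strictly positive and finite",
         call. = FALSE)
  }
  colnames(m) <- behaviors()
  m / rowSums(m)
}

#' Centred log-ratio transform
#'
#' `clr(x)[j] = log x_j - mean(log x)`; a zero-sum real representation of the
#' composition. Scale-invariant, so minutes and proportions give the same
#' result.
#'
#' @param x A `composition` or positive 4-vector.
#' @return Named numeric 4-vector summing to zero.
#' @export
clr <- function(x) {
  p <- unclass(closure(x))
  v <- log(p)
  attributes(v) <- list(names = names(p))
  v - mean(v)
}

# Row-wise clr of an n x 4 positive matrix.
clr_matrix <- function(m) {
  lv <- log(m)
  lv - rowMeans(lv)
}

#' Pivot coordinate basis
#'
#' An orthonormal isometric log-ratio basis whose first coordinate contrasts
#' one chosen behavior against the geometric mean of the remaining three:
#' the pivot-coordinate construction used to read each behavior "versus the
#' remaining behaviors". Non-pivot parts keep their canonical relative order;
#' any other order changes only the 2nd/3rd coordinates, never the first
#' coordinate or any model fit expressed in the basis.
#'
#' @param pivot_part Behavior placed first ("sleep", "sed", "lpa" or "mvpa").
#' @return A `pivot_basis`: list with `pivot_part`, `order` (permutation of
#'   the behaviors) and `V`, the 4 x 3 contrast matrix with orthonormal,
#'   zero-sum columns so that `z = t(V) %*% clr(x)`.
#' @export
pivot_basis <- function(pivot_part = "sleep") {
  b <- behaviors()
  pivot_part <- match.arg(tolower(pivot_part), b)
  ord <- c(pivot_part, setdiff(b, pivot_part))
  D <- 4L
  V_ord <- matrix(0, nrow = D, ncol = D - 1L)
  for (k in seq_len(D - 1L)) {
    s <- sqrt((D - k) / (D - k + 1))
    V_ord[k, k] <- s
    V_ord[(k + 1):D, k] <- -s / (D - k)
  }
  V <- V_ord[match(b, ord), , drop = FALSE]
  rownames(V) <- b
  structure(list(pivot_part = pivot_part, order = ord, V = V),
            class = "pivot_basis")
}

#' Pivot (ilr) coordinates of a composition
#'
#' Maps a 4-part composition to 3 unconstrained real coordinates in the given
#' behavior-first basis. The first coordinate is
#' `sqrt(3/4) * log(pivot part / geometric mean of the others)`.
#'
#' @param x A `composition` or positive 4-vector.
#' @param basis A [pivot_basis()] (default sleep-first).
#' @return Numeric 3-vector.
#' @export
pivot_coord <- function(x, basis = pivot_basis("sleep")) {
  drop(crossprod(basis$V, clr(x)))
}

# Row-wise pivot coordinates of an n x 4 minutes/proportions matrix.
pivot_coord_matrix <- function(m, basis = pivot_basis("sleep")) {
  clr_matrix(comp_matrix(m)) %*% basis$V
}

#' Inverse pivot transform
#'
#' @param z Finite numeric 3-vector of pivot coordinates.
#' @param basis A [pivot_basis()].
#' @param day_minutes Day length attached to the result.
#' @return A `composition` in canonical part order.
#' @rdname pivot_coord
#' @export
pivot_inv <- function(z, basis = pivot_basis("sleep"), day_minutes = 1440) {
  if (length(z) != 3L || any(!is.finite(z))) {
    stop("pivot coordinates must be a finite 3-vector", call. = FALSE)
  }
  composition(exp(drop(basis$V %*% z)), day_minutes = day_minutes)
}

# Row-wise inverse pivot: n x 3 matrix -> n x 4 closed matrix.
pivot_inv_matrix <- function(z, basis = pivot_basis("sleep")) {
  m <- exp(z %*% t(basis$V))
  m <- m / rowSums(m)
  colnames(m) <- behaviors()
  m
}

#' First pivot coordinate of every behavior
#'
#' For each behavior j, the first coordinate of the pivot basis with j placed
#' first: `sqrt(3/4) * log(x_j / geometric mean of the other three)`.
#' Algebraically `sqrt(4/3) * clr(x)`, hence the four values sum to zero --
#' the identity that makes the four published "versus remaining" coefficients
#' of a fitted model sum to zero.
#'
#' @param x A `composition` or positive 4-vector.
#' @return Named numeric 4-vector summing to zero.
#' @export
first_pivot_all <- function(x) {
  sqrt(4 / 3) * clr(x)
}
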