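# Evaluation/search domain construction: merge anatomical masks and dilate,
# compensating for registration and brain-extraction inaccuracies.

#' Voxel-wise union of binary masks
#'
#' @param masks A list of grid-compatible [binary_mask()]s (at least one).
#' @return A [binary_mask()] marking the union.
#' @export
merge_masks <- function(masks) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  if (length(masks) < 1L) stop("at least one mask required", call. = FALSE)
  out <- masks[[1]]$data
  for (m in masks[-1]) {
    .stop_incompatible(masks[[1]], m, "masks")
    out <- out | m$data
  }
  binary_mask(out, affine = masks[[1]]$affine)
}

# one 6-connected (3D cross) dilation step, clipped at the grid boundary
.dilate_once6 <- function(a) {
  d <- dim(a); out <- a
  out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  out[-1, , ]    <- out[-1, , ]    | a[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  out[, -1, ]    <- out[, -1, ]    | a[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  out[, , -1]    <- out[, , -1]    | a[, , -d[3]]
  out
}

#' Iterative binary dilation with a 6-connected structuring element
#'
#' Each iteration grows the mask by one voxel along the six face-adjacent
#' directions (a 3D cross element); after `k` iterations an isolated voxel
#' becomes the Manhattan ball of radius `k`. Dilation is clipped at the grid
#' boundary and never extends beyond the image.
#'
#' @param mask A [binary_mask()].
#' @param iterations Non-negative iteration count; `0` returns the input
#'   unchanged.
#' @return The dilated [binary_mask()] (a superset of the input).
#' @export
dilate_mask <- function(mask, iterations) {
  stopifnot(inherits(mask, "binary_mask"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("'iterations' must be a non-negative integer", call. = FALSE)
  a <- mask$data
  for (i in seq_len(iterations)) a <- .dilate_once6(a)
  binary_mask(a, affine = mask$affine)
}

#' Build the evaluation/search domain from anatomical masks
#'
#' Merges the brain mask with an optional medulla mask (the lower medulla is
#' commonly clipped by brain-extraction tools yet can harbor CNS tumors) and
#' dilates the union for a fixed number of 6-connected iterations to absorb
#' registration and extraction inaccuracies. All delineation and voxel-level
#' evaluation is restricted to this domain.
#'
#' @param brain_mask A [binary_mask()] of the extracted brain.
#' @param medulla_mask Optional grid-compatible [binary_mask()] of the
#'   medulla; merged with the brain mask when supplied.
#' @param iterations Dilation iterations; default 20.
#' @return A `fet_domain_mask` object: `mask` (the dilated union) plus
#'   provenance (`sources`, `iterations`).
#' @export
build_domain <- function(brain_mask, medulla_mask = NULL, iterations = 20) {
  src <- c("brain", if (!is.null(medulla_mask)) "medulla")
  merged <- merge_masks(c(list(brain_mask),
                          if (!is.null(medulla_mask)) list(medulla_mask)))
  dil <- dilate_mask(merged, iterations)
  if (!any(dil$data)) stop("domain mask is empty", call. = FALSE)
  structure(list(mask = dil, sources = src,
                 iterations = as.integer(iterations)),
            class = "fet_domain_mask")
}

#' Coerce a mask to a domain-mask object
#'
#' @param x A `fet_domain_mask` or a [binary_mask()] (wrapped with zero
#'   recorded dilation).
#' @return A `fet_domain_mask`.
#' @export
as_domain <- function(x) {
  if (inherits(x, "fet_domain_mask")) return(x)
  if (inherits(x, "binary_mask")) {
    if (!any(x$data)) stop("domain mask is empty", call. = FALSE)
    return(structure(list(mask = x, sources = "mask", iterations = 0L),
                     class = "fet_domain_mask"))
  }
  stop("cannot interpret object as a domain mask", call. = FALSE)
}

#' @export
print.fet_domain_mask <- function(x, ...) {
  cat(sprintf("<domain mask> sources: %s; %d dilation iterations; %d voxels\n",
              paste(x$sources, collapse = "+"), x$iterations,
              sum(x$mask$data)))
  invisible(x)
}

#' Restrict a volume or mask to a domain
#'
#' Voxels outside the domain are set to zero (volumes) or `FALSE` (masks);
#' voxels inside are unchanged.
#'
#' @param x An [image_volume()] or [binary_mask()].
#' @param domain A `fet_domain_mask` or [binary_mask()].
#' @return An object of the same kind as `x`.
#' @export
restrict_to_domain <- function(x, domain) {
  dom <- as_domain(domain)$mask
  .stop_incompatible(x, dom, "volume and domain")
  if (inherits(x, "binary_mask"))
    binary_mask(x$data & dom$data, affine = x$affine)
  else
    image_volume(x$data * dom$data, affine = x$affine)
}
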