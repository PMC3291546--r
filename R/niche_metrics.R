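# Distance-based niche statistics in the two-dimensional isotope space
# spanned by delta13C and delta15N: group centroids and centroid distances
# (total niche breadth), the two-tissue individual niche breadth, dispersion
# of intra-individual difference vectors, and the WIC/TNW specialization
# index. Centroids are arithmetic means, so the sum-of-squared-distances
# decomposition into within- and between-individual parts is exact.

iso_mat <- function(x) cbind(d13c = x$d13c, d15n = x$d15n)

euclid <- function(m, centre) sqrt((m[, 1] - centre[1])^2 +
                                   (m[, 2] - centre[2])^2)

group_id <- function(s, grouping) {
  switch(grouping,
         habitat_age = paste(s$habitat, s$age, sep = "."),
         habitat_age_tissue = paste(s$habitat, s$age, s$tissue, sep = "."),
         stop("unknown grouping: ", grouping, call. = FALSE))
}

#' Centroid of a cloud of isotope points
#'
#' The componentwise arithmetic mean, i.e. the centre used in a multivariate
#' variance decomposition of Euclidean distances.
#'
#' @param points Data frame or matrix with columns \code{d13c}, \code{d15n}
#'   (a two-column unnamed matrix is accepted).
#' @return Named numeric vector \code{c(d13c, d15n)}.
#' @export
#' @examples
#' group_centroid(data.frame(d13c = c(-20, -18), d15n = c(8, 10)))
group_centroid <- function(points) {
  m <- if (is.data.frame(points)) iso_mat(points) else as.matrix(points)
  if (!nrow(m)) stop("cannot take the centroid of zero points", call. = FALSE)
  if (ncol(m) != 2L) stop("isotope points are two-dimensional", call. = FALSE)
  c(d13c = mean(m[, 1]), d15n = mean(m[, 2]))
}

#' Euclidean distances from each sample to its group centroid
#'
#' The per-sample response used for total niche breadth: each sample's
#' Euclidean distance in (delta13C, delta15N) space to the centroid of its
#' own group. The default grouping (habitat x age x tissue) matches the
#' population-niche analysis; \code{"habitat_age"} pools tissues and is the
#' granularity used inside the WIC/TNW index.
#'
#' @param s A [sample_set()].
#' @param grouping \code{"habitat_age_tissue"} (default) or
#'   \code{"habitat_age"}.
#' @return Data frame: one row per sample with its factors, coordinates,
#'   \code{group} label and \code{distance} (per mil).
#' @export
centroid_distances <- function(s,
                               grouping = c("habitat_age_tissue",
                                            "habitat_age")) {
  stopifnot(inherits(s, "sample_set"))
  grouping <- match.arg(grouping)
  bad <- !s$habitat %in% iso_habitats | !s$age %in% iso_ages |
    !s$tissue %in% iso_tissues
  if (any(bad))
    stop("sample(s) with undefined group at row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  g <- group_id(s, grouping)
  m <- iso_mat(s)
  distance <- numeric(nrow(s))
  for (lev in unique(g)) {
    idx <- which(g == lev)
    cen <- group_centroid(m[idx, , drop = FALSE])
    distance[idx] <- euclid(m[idx, , drop = FALSE], cen)
  }
  data.frame(individual_id = s$individual_id, province = s$province,
             habitat = s$habitat, age = s$age, tissue = s$tissue,
             d13c = s$d13c, d15n = s$d15n, group = g, distance = distance,
             stringsAsFactors = FALSE)
}

#' Total niche width of one habitat x age group
#'
#' TNW is the average Euclidean distance from each sample of the group to
#' the group centroid, tissues pooled.
#'
#' @param s A [sample_set()].
#' @param habitat,age Group selectors.
#' @param tissues Tissues to include (default all present).
#' @return TNW in per mil.
#' @export
total_niche_width <- function(s, habitat, age, tissues = iso_tissues) {
  stopifnot(inherits(s, "sample_set"))
  sub <- s[s$habitat == habitat & s$age == age & s$tissue %in% tissues, ,
           drop = FALSE]
  if (nrow(sub) < 2L)
    stop(sprintf("group %s/%s has fewer than 2 samples", habitat, age),
         call. = FALSE)
  m <- iso_mat(sub)
  mean(euclid(m, group_centroid(m)))
}

#' Two-tissue contrast for one individual
#'
#' The muscle-minus-collagen difference vector and its Euclidean norm
#' ("individual niche breadth"). Requires both tissues; dispersion results
#' downstream are invariant to a global sign flip of the convention.
#'
#' @param s A [sample_set()].
#' @param individual_id The individual.
#' @return List with \code{individual_id}, \code{diff} (named vector, per
#'   mil) and \code{breadth} (per mil).
#' @export
individual_contrast <- function(s, individual_id) {
  stopifnot(inherits(s, "sample_set"))
  rows <- s[s$individual_id == individual_id, , drop = FALSE]
  mus <- rows[rows$tissue == "muscle", , drop = FALSE]
  col <- rows[rows$tissue == "collagen", , drop = FALSE]
  if (nrow(mus) != 1L || nrow(col) != 1L)
    stop(sprintf("insufficient tissues for individual '%s': need one muscle and one collagen sample",
                 individual_id), call. = FALSE)
  diff <- c(d13c = mus$d13c - col$d13c, d15n = mus$d15n - col$d15n)
  list(individual_id = individual_id, diff = diff,
       breadth = sqrt(sum(diff^2)))
}

#' Two-tissue contrasts for every qualifying individual
#'
#' @param s A [sample_set()].
#' @return Data frame: one row per individual possessing both muscle and
#'   collagen, with the difference components \code{dc}, \code{dn} and the
#'   \code{breadth} (Euclidean norm). Individuals lacking a tissue are
#'   silently excluded; use [validate_sample_set()] to enumerate them.
#' @export
individual_contrasts <- function(s) {
  stopifnot(inherits(s, "sample_set"))
  ids <- unique(s$individual_id)
  keep <- vapply(ids, function(id) {
    tis <- s$tissue[s$individual_id == id]
    sum(tis == "muscle") == 1L && sum(tis == "collagen") == 1L
  }, logical(1))
  ids <- ids[keep]
  if (!length(ids))
    stop("no individual has both a muscle and a collagen sample",
         call. = FALSE)
  rows <- lapply(ids, function(id) {
    ic <- individual_contrast(s, id)
    first <- s[s$individual_id == id, , drop = FALSE][1L, ]
    data.frame(individual_id = id, province = first$province,
               habitat = first$habitat, age = first$age,
               dc = unname(ic$diff[1]), dn = unname(ic$diff[2]),
               breadth = ic$breadth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# muscle+collagen rows of individuals that have both tissues
paired_subset <- function(s, habitat = NULL, age = NULL) {
  sub <- s
  if (!is.null(habitat)) sub <- sub[sub$habitat == habitat, , drop = FALSE]
  if (!is.null(age)) sub <- sub[sub$age == age, , drop = FALSE]
  sub <- sub[sub$tissue %in% c("muscle", "collagen"), , drop = FALSE]
  if (!nrow(sub)) return(sub)
  both <- tapply(sub$tissue, sub$individual_id,
                 function(t) all(c("muscle", "collagen") %in% t))
  sub[sub$individual_id %in% names(both)[both], , drop = FALSE]
}

#' Within-individual component of niche width for one group
#'
#' WIC is the average Euclidean distance from muscle and collagen samples to
#' their own individual's centroid, taken over all such samples in the
#' habitat x age group. With exactly two tissues each sample sits at half
#' the muscle-collagen pair distance, so each individual's contrast breadth
#' equals exactly twice its per-sample WIC contribution.
#'
#' @param s A [sample_set()].
#' @param habitat,age Group selectors.
#' @return WIC in per mil.
#' @export
within_individual_component <- function(s, habitat, age) {
  sub <- paired_subset(s, habitat, age)
  if (!nrow(sub))
    stop(sprintf("group %s/%s has no individual with both muscle and collagen",
                 habitat, age), call. = FALSE)
  d <- numeric(nrow(sub))
  m <- iso_mat(sub)
  for (id in unique(sub$individual_id)) {
    idx <- which(sub$individual_id == id)
    cen <- group_centroid(m[idx, , drop = FALSE])
    d[idx] <- euclid(m[idx, , drop = FALSE], cen)
  }
  mean(d)
}

#' Dispersion of intra-individual difference vectors
#'
#' Within each habitat x age group, the Euclidean distance of each
#' individual's muscle-minus-collagen difference vector to the group
#' centroid of those difference vectors — a measure of between-individual
#' variation in individual niche breadth (how diverse the individual
#' strategies are), as opposed to its average.
#'
#' @param contrasts Output of [individual_contrasts()].
#' @return \code{contrasts} with a \code{group} label and \code{distance}
#'   column appended.
#' @export
difference_dispersion <- function(contrasts) {
  stopifnot(is.data.frame(contrasts),
            all(c("dc", "dn", "habitat", "age") %in% names(contrasts)))
  if (!nrow(contrasts)) stop("no contrasts supplied", call. = FALSE)
  g <- paste(contrasts$habitat, contrasts$age, sep = ".")
  m <- cbind(contrasts$dc, contrasts$dn)
  distance <- numeric(nrow(contrasts))
  for (lev in unique(g)) {
    idx <- which(g == lev)
    cen <- group_centroid(m[idx, , drop = FALSE])
    distance[idx] <- euclid(m[idx, , drop = FALSE], cen)
  }
  out <- contrasts
  out$group <- g
  out$distance <- distance
  out
}

#' WIC/TNW individual-specialization index for one group
#'
#' The ratio of the within-individual component to the total niche width of
#' a habitat x age group. Values near 0 indicate individually specialized
#' populations (individual niches much narrower than the population niche);
#' values near 1 indicate individual generalists spanning the population
#' niche. Both numerator and denominator are computed on the same sample
#' universe — muscle and collagen samples of individuals possessing both —
#' with the TNW centroid at the habitat x age level (the default,
#' \code{tnw_scope = "paired"}). \code{tnw_scope = "all_tissues"} instead
#' divides by the group TNW over every sample and is flagged in the output.
#'
#' @param s A [sample_set()].
#' @param habitat,age Group selectors.
#' @param tnw_scope \code{"paired"} (default) or \code{"all_tissues"}.
#' @return One-row data frame: group factors, \code{n_samples},
#'   \code{n_individuals}, \code{tnw}, \code{wic}, \code{wic_tnw},
#'   \code{tnw_scope}.
#' @export
specialization_index <- function(s, habitat, age,
                                 tnw_scope = c("paired", "all_tissues")) {
  tnw_scope <- match.arg(tnw_scope)
  sub <- paired_subset(s, habitat, age)
  if (!nrow(sub))
    stop(sprintf("group %s/%s has no individual with both muscle and collagen",
                 habitat, age), call. = FALSE)
  wic <- within_individual_component(s, habitat, age)
  tnw <- if (tnw_scope == "paired") {
    m <- iso_mat(sub)
    mean(euclid(m, group_centroid(m)))
  } else {
    total_niche_width(s, habitat, age)
  }
  if (tnw <= 0)
    stop(sprintf("group %s/%s has zero total niche width; WIC/TNW undefined",
                 habitat, age), call. = FALSE)
  data.frame(habitat = habitat, age = age, n_samples = nrow(sub),
             n_individuals = length(unique(sub$individual_id)),
             tnw = tnw, wic = wic, wic_tnw = wic / tnw,
             tnw_scope = tnw_scope, stringsAsFactors = FALSE)
}

#' Per-group niche metrics table
#'
#' One row per observed habitat x age combination with TNW, WIC and
#' WIC/TNW. Combinations with no muscle+collagen individual or zero TNW are
#' skipped with a warning rather than failing the whole run.
#'
#' @param s A [sample_set()].
#' @param tnw_scope Passed to [specialization_index()].
#' @return Data frame, one row per computable group.
#' @export
niche_metrics <- function(s, tnw_scope = c("paired", "all_tissues")) {
  stopifnot(inherits(s, "sample_set"))
  tnw_scope <- match.arg(tnw_scope)
  cells <- unique(s[, c("habitat", "age")])
  cells <- cells[order(cells$habitat, cells$age), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    row <- tryCatch(
      specialization_index(s, cells$habitat[i], cells$age[i], tnw_scope),
      error = function(e) {
        warning(sprintf("skipping group %s/%s: %s", cells$habitat[i],
                        cells$age[i], conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no computable group", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
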