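# Randomly partition n items into k near-equal groups; remainders are
# spread over randomly chosen groups. Returns a list of index vectors.
randomPartition <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k)
  if (extra > 0L)
    sizes[sample.int(k, extra)] <- base + 1L
  idx <- sample.int(n)
  split(idx, rep(seq_len(k), sizes))
}

#' Form object-level super-trials
#'
#' For every object condition, the available trials are randomly assigned
#' to `nGroups` near-equal groups and averaged within each group, yielding
#' `nGroups` super-trials (pseudo-trials) per object. Each raw trial
#' contributes to exactly one super-trial; the assignment is recorded in
#' the provenance.
#'
#' @param epochs an [EpochArray-class] (one-back repeats should already
#'   have been dropped, see [dropOneBack()]).
#' @param nGroups number of super-trials per condition (default 3).
#' @param seed integer seed for the random partition, or NULL.
#' @return a [SuperTrialSet-class] with scheme "object".
#' @export
makeObjectSupertrials <- function(epochs, nGroups = 3L, seed = NULL) {
  stopifnot(is(epochs, "EpochArray"))
  nGroups <- as.integer(nGroups)
  meta <- epochs@trialMeta
  conds <- sort(unique(meta$object_id))
  d <- dim(epochs@data)
  counts <- table(meta$object_id)
  short <- names(counts)[counts < nGroups]
  if (length(short))
    stop(sprintf("condition(s) with fewer trials than groups: %s",
                 paste(short, collapse = ", ")))
  out <- array(0, dim = c(length(conds), nGroups, d[2], d[3]))
  prov <- vector("list", length(conds))
  withSeed(seed, {
    for (ci in seq_along(conds)) {
      idx <- which(meta$object_id == conds[ci])
      part <- randomPartition(length(idx), nGroups)
      prov[[ci]] <- lapply(part, function(p) idx[p])
      for (g in seq_len(nGroups)) {
        sel <- idx[part[[g]]]
        out[ci, g, , ] <- colMeans(epochs@data[sel, , , drop = FALSE],
                                   dims = 1)
      }
    }
  })
  names(prov) <- conds
  new("SuperTrialSet", conditions = conds, data = out,
      timeMs = epochs@timeMs, scheme = "object",
      dimension = NA_character_, provenance = prov, normalized = FALSE)
}

# Average trials per object: list(data = objects x channels x time array,
# objects = ids in array order).
objectAverages <- function(epochs) {
  meta <- epochs@trialMeta
  conds <- sort(unique(meta$object_id))
  d <- dim(epochs@data)
  out <- array(0, dim = c(length(conds), d[2], d[3]))
  for (ci in seq_along(conds)) {
    idx <- which(meta$object_id == conds[ci])
    out[ci, , ] <- colMeans(epochs@data[idx, , , drop = FALSE], dims = 1)
  }
  list(data = out, objects = conds)
}

#' Form category-level super-trials
#'
#' Trials are first averaged per object condition; the object averages are
#' then sorted by their level on one category dimension, and within each
#' level randomly partitioned into `nGroups` groups and averaged, giving
#' `nGroups` super-trials per category level. Because every object's
#' average enters exactly one super-trial (recorded in the provenance),
#' leave-one-super-trial-out cross-validation never trains and tests on
#' the same object.
#'
#' @param epochs an [EpochArray-class].
#' @param stimset the [StimulusSet-class] providing the category labels.
#' @param dimension name of the category dimension to sort by.
#' @param nGroups number of super-trials per level (default 3).
#' @param seed integer seed, or NULL.
#' @return a [SuperTrialSet-class] with scheme "category"; conditions are
#'   the two levels of `dimension`, provenance lists the object ids.
#' @export
makeCategorySupertrials <- function(epochs, stimset, dimension,
                                    nGroups = 3L, seed = NULL) {
  stopifnot(is(epochs, "EpochArray"), is(stimset, "StimulusSet"))
  nGroups <- as.integer(nGroups)
  if (!dimension %in% dimensionNames(stimset))
    stop(sprintf("dimension '%s' not present in the stimulus set",
                 dimension))
  avg <- objectAverages(epochs)
  labels <- categoryLabels(stimset)[avg$objects, dimension]
  categorySupertrialsCore(avg, labels, dimension, nGroups, seed,
                          epochs@timeMs)
}

# category super-trials from precomputed object averages (labels is a
# two-level factor aligned with avg$objects)
categorySupertrialsCore <- function(avg, labels, dimension, nGroups,
                                    seed, timeMs) {
  lev <- levels(labels)
  d <- dim(avg$data)
  out <- array(0, dim = c(2L, nGroups, d[2], d[3]))
  prov <- vector("list", 2L)
  withSeed(seed, {
    for (li in 1:2) {
      objIdx <- which(labels == lev[li])
      if (length(objIdx) < nGroups)
        stop(sprintf(
          "level '%s' has fewer objects (%d) than groups (%d)",
          lev[li], length(objIdx), nGroups))
      part <- randomPartition(length(objIdx), nGroups)
      prov[[li]] <- lapply(part, function(p) avg$objects[objIdx[p]])
      for (g in seq_len(nGroups)) {
        sel <- objIdx[part[[g]]]
        out[li, g, , ] <- colMeans(avg$data[sel, , , drop = FALSE],
                                   dims = 1)
      }
    }
  })
  names(prov) <- lev
  new("SuperTrialSet", conditions = lev, data = out,
      timeMs = timeMs, scheme = "category", dimension = dimension,
      provenance = prov, normalized = FALSE)
}
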