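# Shared fixtures and oracle helpers, all built in code.

# rasterized disk / rectangle label matrices for shape oracles
make_disk_label <- function(radius, size = 4 * radius + 20,
                            center = c(size / 2, size / 2)) {
  lab <- matrix(0L, size, size)
  for (r in seq_len(size))
    for (cc in seq_len(size))
      if ((r - center[1])^2 + (cc - center[2])^2 <= radius^2)
        lab[r, cc] <- 1L
  lab
}

make_rect_label <- function(h, w, size = c(h + 40, w + 40),
                            at = c(21, 21)) {
  lab <- matrix(0L, size[1], size[2])
  lab[at[1]:(at[1] + h - 1), at[2]:(at[2] + w - 1)] <- 1L
  lab
}

blank_field <- function(lab) {
  imageField(list(nuclear = matrix(0, nrow(lab), ncol(lab))))
}

# majority-pixel-overlap matching of detections against the generator's
# ground-truth nucleus map: a detection is matched to the truth object
# owning >= 50% of its truth-covered pixels, unless a second object owns
# > 30% (an ambiguous merge, which counts against segmentation, not the
# viability rule)
match_to_truth <- function(seg, truth) {
  rec <- seg$records[seg$records$qc_pass, , drop = FALSE]
  tm <- truth$nucleusMap
  truth_id <- rep(NA_integer_, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    own <- tm[seg$labelMap == rec$label[i]]
    tt <- table(own[own > 0])
    if (!length(tt)) next
    best <- which.max(tt)
    sh1 <- as.numeric(tt[best]) / length(own)
    sh2 <- if (length(tt) >= 2)
      sort(as.numeric(tt), decreasing = TRUE)[2] / length(own) else 0
    if (sh1 >= 0.5 && sh2 <= 0.3)
      truth_id[i] <- as.integer(names(tt)[best])
  }
  cbind(rec, truth_id = truth_id)
}

# deterministic split of a labeled feature table into a fixed-size
# training part per class and a held-out remainder
split_controls <- function(pop, nTrain, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(pop)), pop$true_class),
                       function(ii) sample(ii, nTrain)))
  list(train = pop[idx, , drop = FALSE],
       holdout = pop[-idx, , drop = FALSE])
}

feature_cols <- function(pop) setdiff(names(pop), "true_class")
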