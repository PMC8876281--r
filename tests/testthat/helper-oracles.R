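# Shared fixtures and independent brute-force oracles. The oracles use
# plain voxel loops / pair enumeration on purpose: they must stay
# independent of the vectorized implementation paths they check.

small_atlas <- function() build_atlas(c(8, 48, 48), c(5, 0.5, 0.5))

empty_lesion <- function(atlas) {
  lesion_mask(array(FALSE, dim(atlas$labels$data)), atlas$spacing)
}

# Brute-force voxel count of `lab == label` by an explicit triple loop.
loop_count_label <- function(lab, label) {
  d <- dim(lab)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (lab[i, j, k] == label) n <- n + 1L
  n
}

# Brute-force overlap count |lesion & (lab == label)| by an explicit loop.
loop_count_overlap <- function(lab, les, label) {
  d <- dim(lab)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (lab[i, j, k] == label && les[i, j, k]) n <- n + 1L
  n
}

# Brute-force AUC by enumerating every positive x negative pair (ties 1/2).
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Fast rank-based AUC used only inside the bootstrap oracle.
rank_auc <- function(scores, y) {
  n1 <- sum(y == 1)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * sum(y == 0))
}

# One-voxel lesion in each territory of `labels_on` (character names).
point_lesion <- function(atlas, labels_on) {
  les <- array(FALSE, dim(atlas$labels$data))
  for (nm in labels_on) {
    idx <- which(atlas$labels$data == match(nm, structure_names()))[1]
    les[idx] <- TRUE
  }
  lesion_mask(les, atlas$spacing)
}

# Ten slices of a 96x96 phantom with a lesion: the standard desk-scale
# segmentation fixture.
seg_fixture <- function(noise_seed = 4) {
  atlas <- build_atlas(c(10, 96, 96))
  lesion <- place_lesion(atlas, c(pons = 0.3, left_cerebellum = 0.2), seed = 3)
  vol <- render_ct(atlas, lesion, seed = noise_seed)
  list(atlas = atlas,
       images = lapply(1:10, function(s) vol[s, , ]),
       labels = lapply(1:10, function(s) atlas$labels$data[s, , ]))
}
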