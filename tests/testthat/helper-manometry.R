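# Labeling protocol for classifier training: a window is phase III when
# its midpoint lies inside a labeled phase-III segment of its region.
label_phase3_windows <- function(feats, labels) {
  feats$phase3 <- FALSE
  for (k in seq_len(nrow(labels))) {
    L <- labels[k, ]
    hit <- feats$region == L$region &
      feats$t_mid_h >= L$start_h & feats$t_mid_h <= L$end_h
    feats$phase3 <- feats$phase3 | hit
  }
  feats
}

# Train the default classifier on a few synthetic traces with known
# phase-III placement.
train_synthetic_classifier <- function(cfg, subject_idx = 1:6,
                                       l2_penalty = 1e-2) {
  train <- do.call(rbind, lapply(subject_idx, function(i) {
    s <- list(subject = sprintf("S%03d", i),
              physiology = list(TMMC = 1 + 0.3 * i))
    gm <- generate_manometry(cfg, s)
    label_phase3_windows(extract_features(gm$trace), gm$labels)
  }))
  list(classifier = train_phase3_classifier(train, l2_penalty),
       features = train)
}
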