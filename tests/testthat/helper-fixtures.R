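# Fixture builders: small cohorts assembled in code.

# the worked-example distress series
distress_series <- c(2, 1, 1, 2, 3, 2, 2, 1)

# a minimal valid cohort: n participants x the given emotions x 8 occasions,
# deterministic scores unless a score function is supplied
tiny_cohort <- function(n_participants = 2,
                        emotions = c(interest = "positive", distress = "negative"),
                        n_occasions = 8,
                        score_fn = function(p, e) rep(3L, n_occasions),
                        conceptual = NULL, performative = NULL) {
  pids <- paste0("P", seq_len(n_participants))
  ratings <- do.call(rbind, lapply(pids, function(p) {
    do.call(rbind, lapply(names(emotions), function(e) {
      data.frame(participant = p, emotion = e, occasion = seq_len(n_occasions),
                 score = as.integer(score_fn(p, e)))
    }))
  }))
  grid <- expand.grid(occasion = seq_len(n_occasions), participant = pids,
                      stringsAsFactors = FALSE)
  complexity <- data.frame(
    participant = grid$participant,
    occasion = grid$occasion,
    conceptual = if (is.null(conceptual)) rep(3L, nrow(grid)) else conceptual,
    performative = if (is.null(performative)) rep(3L, nrow(grid)) else performative
  )
  ratings_dataset(ratings, complexity, emotions)
}

# write a long-format CSV by hand (independent of write_ratings)
write_cohort_csv <- function(path, rows) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
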