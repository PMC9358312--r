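# Shared fixtures and independent oracles used across the test files.

# minimal events table builder
make_events <- function(time_s, sender = "A", recipient = "B",
                        context = "play", session = "s1",
                        type = "sia01", modality = "visual",
                        attentive = "true", responded = "false") {
  n <- length(time_s)
  data.frame(
    event_id = sprintf("e%03d", seq_len(n)),
    session_id = rep_len(session, n),
    time_s = time_s,
    sender_id = rep_len(sender, n),
    recipient_id = rep_len(recipient, n),
    gesture_type = rep_len(type, n),
    modality = rep_len(modality, n),
    recipient_attentive = rep_len(attentive, n),
    responded = rep_len(responded, n),
    context = rep_len(context, n),
    sequence_id = "",
    stringsAsFactors = FALSE)
}

# independent segmentation oracle: transitive closure of the "within gap_s
# of an adjacent event in the same stream" relation, components by
# repeated boolean matrix closure (no chaining logic shared with the
# implementation)
oracle_sequences <- function(events, gap_s = 5) {
  ev <- events[order(events$session_id, events$time_s), , drop = FALSE]
  n <- nrow(ev)
  A <- diag(n) > 0
  key <- paste(ev$session_id, ev$sender_id, ev$recipient_id, ev$context)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || key[i] != key[j]) next
      ti <- ev$time_s[i]; tj <- ev$time_s[j]
      # adjacent within the stream and within the window
      between <- key == key[i] & ev$time_s > min(ti, tj) & ev$time_s < max(ti, tj)
      if (abs(ti - tj) <= gap_s && !any(between)) A[i, j] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      lab <- lab + 1L
      comp[A[i, ]] <- lab
    }
  }
  sizes <- tabulate(comp)
  list(component = comp, in_sequence = sizes[comp] >= 2, event_id = ev$event_id)
}

# random event stream for property tests
random_stream <- function(n, seed) {
  set.seed(seed)
  make_events(
    time_s = sort(round(runif(n, 0, 40), 1)),
    sender = sample(c("A", "B"), n, replace = TRUE),
    recipient = sample(c("X", "Y"), n, replace = TRUE),
    context = sample(c("play", "groom"), n, replace = TRUE),
    session = sample(c("s1", "s2"), n, replace = TRUE))
}

# small synthetic config for fast end-to-end tests
small_config <- function(...) {
  synthetic_config(
    groups = data.frame(
      group_id = c("gc", "go", "gs"),
      species = c("chimpanzee", "orangutan", "siamang"),
      size = c(6L, 5L, 5L), stringsAsFactors = FALSE),
    sessions = list(
      chimpanzee = list(n_sessions = 12L, session_length_s = 300),
      orangutan = list(n_sessions = 16L, session_length_s = 900),
      siamang = list(n_sessions = 16L, session_length_s = 900)),
    scans_per_individual = 20L,
    ...)
}

# flat null config: no planted effects, species intercepts equalized
null_config <- function() {
  synthetic_config(
    beta_age_attention = 0, beta_age_attention_visual = 0,
    beta_bond_dyadrep = 0, beta_age_seq = 0, beta_centrality_seq = 0,
    beta_age_response = 0, beta_seq_response = 0,
    beta_attention_response = 0,
    attention_intercept = c(chimpanzee = 2.0, orangutan = 2.0, siamang = 2.0),
    sequence_intercept = stats::qlogis(c(chimpanzee = 0.35, orangutan = 0.35,
                                         siamang = 0.35)),
    response_intercept = stats::qlogis(c(chimpanzee = 0.65, orangutan = 0.65,
                                         siamang = 0.65)),
    dyad_repertoire_intercept = stats::qlogis(c(chimpanzee = 0.15,
                                                orangutan = 0.15,
                                                siamang = 0.15)))
}
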