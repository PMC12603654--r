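# shared fixtures, all generated in code

# deterministic event table: given durations, space onsets `clearance` apart
# (plus block gaps every `block_size` events)
manual_events <- function(durations, clearance = 0, block_size = Inf,
                          inter_block_interval = 5, trial_type = "event") {
  n <- length(durations)
  step <- durations + clearance
  block <- (seq_len(n) - 1) %/% block_size
  extra <- c(ifelse(diff(block) != 0, inter_block_interval, 0))
  onset <- c(0, cumsum(step[-n] + extra))
  tibble::tibble(onset = onset, duration = durations, trial_type = trial_type)
}

# render several event tables (possibly different kernels / fixed durations)
# into one continuous signal of common length
render_multi <- function(event_list, spec_list, sfreq, total_padding = 2,
                         fixed_durations = NULL) {
  sigs <- lapply(seq_along(event_list), function(i) {
    ev <- event_list[[i]]
    if (!is.null(fixed_durations)) ev$duration <- fixed_durations[i]
    render_continuous(ev, spec_list[[i]], total_padding = total_padding)
  })
  n <- max(vapply(sigs, function(s) ncol(s$data), integer(1)))
  y <- numeric(n)
  for (s in sigs) y[seq_len(ncol(s$data))] <- y[seq_len(ncol(s$data))] + s$data[1, ]
  signal(y, sfreq = sfreq, t0 = -total_padding)
}

# small sweep configuration used by evaluation tests
test_config <- function(...) {
  sweep_config(sfreq = 50, repetitions = 20, ...)
}
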