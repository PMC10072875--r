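# Shared fixtures built in code.

# minimal hand-built session: explicit timestamps, all invariants satisfied
make_session <- function(outcomes = c("correct", "incorrect", "correct"),
                         cue_len = 2, chosen = NULL, duration = NULL) {
  n <- length(outcomes)
  init <- seq(10, by = 50, length.out = n)
  if (is.null(duration)) duration <- max(600, init[n] + 60)
  cue_on <- init + 0.5
  cue_off <- cue_on + cue_len
  correct_port <- rep(c("L", "R"), length.out = n)
  if (is.null(chosen)) {
    chosen <- ifelse(outcomes == "correct", correct_port,
              ifelse(outcomes == "incorrect",
                     ifelse(correct_port == "L", "R", "L"), NA))
  }
  choice <- ifelse(outcomes == "omission", NA_real_, cue_off + 0.7)
  session_table(tibble::tibble(
    index = seq_len(n) - 1L, task = "AET", cue_length_s = cue_len,
    delay_s = 0, correct_port = correct_port, chosen_port = chosen,
    init_time_s = init, cue_on_s = cue_on, cue_off_s = cue_off,
    choice_time_s = choice, outcome = outcomes
  ), session_duration_s = duration)
}

# brute-force repetitive-responding oracle: enumerate maximal runs directly
repetitive_oracle <- function(choices) {
  n <- length(choices)
  if (n < 5) return(0)
  blocks <- 0
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && choices[j + 1] == choices[i]) j <- j + 1
    blocks <- blocks + (j - i + 1) %/% 5
    i <- j + 1
  }
  blocks / n
}

# choice-sequence session with arbitrary ports (all responded and correct)
make_choice_session <- function(ports) {
  n <- length(ports)
  init <- seq(10, by = 50, length.out = n)
  session_table(tibble::tibble(
    index = seq_len(n) - 1L, task = "AET", cue_length_s = 2, delay_s = 0,
    correct_port = ports, chosen_port = ports,
    init_time_s = init, cue_on_s = init + 0.5, cue_off_s = init + 2.5,
    choice_time_s = init + 3.2, outcome = "correct"
  ), session_duration_s = max(600, init[n] + 60))
}

# dominant frequency via FFT: independent oracle for spectral peaks
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  ((which.max(sp[-1]) + 1) - 1) * fs / n
}

# random small feature matrix with an imbalanced binary label
make_feature_matrix <- function(n = 200, n_minority = 20, p = 22, seed = 1,
                                shift = 0) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p)
    lab <- rep("majority", n)
    lab[seq_len(n_minority)] <- "minority"
    x[lab == "minority", ] <- x[lab == "minority", ] + shift
    colnames(x) <- paste0("f_", seq_len(p))
    dplyr::bind_cols(tibble::as_tibble(x, .name_repair = "minimal"),
                     tibble::tibble(label = lab))
  })
}
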