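# Independent oracles and small fixtures shared across the suite.

# Reduced-scale run configuration used wherever a full-size cohort would
# add nothing: 32-channel cap, one oddball block of 60 standards + 2 x 10
# deviants (5-trial habituation), shortened FIR.
small_config <- function(n_eeg = 32, two_blocks = FALSE) {
  cfg <- default_config(n_eeg = n_eeg)
  cfg$design$n_standards <- 60
  cfg$design$n_per_deviant <- 10
  cfg$design$habituation_len <- 5
  if (!two_blocks) cfg$design$blocks <- cfg$design$blocks["sicher"]
  cfg$montage$roi_size <- 12
  cfg$stats$grid <- c(16, 16)
  cfg$preproc$filter_length <- 4001
  cfg$stats$n_perm <- 200
  cfg
}

small_montage <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_montage(32, 12)
    cache
  }
})

# Flood-fill connected-component labelling over a full 3D logical array,
# 6-connectivity; written against the array representation (not the
# valid-voxel vector) so it shares no code with the package implementation.
flood_fill_labels <- function(arr) {
  d <- dim(arr)
  lab <- array(0L, d)
  nxt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!arr[i, j, k] || lab[i, j, k] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j, k), 1)
    lab[i, j, k] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        nb <- cur + step
        if (any(nb < 1) || any(nb > d)) next
        if (arr[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff the label pairs biject.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  key <- paste(a[a > 0], b[b > 0])
  length(unique(key)) == length(unique(a[a > 0])) &&
    length(unique(key)) == length(unique(b[b > 0]))
}

# Full sums-of-squares decomposition of a 2x2 within-subject ANOVA
# (subjects x 4 matrix, columns ordered c11, c12, c21, c22).
rm_anova_ss_oracle <- function(vals) {
  n <- nrow(vals)
  y <- aperm(array(t(vals), c(2, 2, n)), c(3, 2, 1))  # y[s, a, b]
  gm <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, m_a, "+") + gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, m_b, "+") + gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  resid <- y
  for (s in seq_len(n)) for (a in 1:2) for (b in 1:2)
    resid[s, a, b] <- y[s, a, b] - m_ab[a, b] - m_sa[s, a] - m_sb[s, b] +
      m_a[a] + m_b[b] + m_s[s] - gm
  ss_abs <- sum(resid^2)
  list(root = ss_a / (ss_as / (n - 1)),
       suffix = ss_b / (ss_bs / (n - 1)),
       interaction = ss_ab / (ss_abs / (n - 1)))
}

# direct scan for post-deviant standards, independent of the package logic
scan_post_deviant <- function(labels, deviants) {
  out <- rep(FALSE, length(labels))
  for (i in seq_along(labels)[-1])
    if (labels[i - 1] %in% deviants && !(labels[i] %in% deviants))
      out[i] <- TRUE
  out
}

make_recording <- function(signal, rate = 200, events = NULL,
                           roles = NULL) {
  n_ch <- nrow(signal)
  if (is.null(roles)) roles <- rep("EEG", n_ch)
  if (is.null(events))
    events <- data.frame(sample = 1L, label = "standard",
                         is_deviant = FALSE, is_habituation = FALSE,
                         is_post_deviant = FALSE)
  mmnpipe:::new_recording(signal, rate,
                          paste0("ch", seq_len(n_ch)), roles, events)
}
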