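# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a clean record + fiducials + windows (no noise), reused across feature tests
clean_beats <- function() {
  fixture("clean_beats", function() {
    cfg <- synth_config(noise_sd_mV = 0, wander_amp_mV = 0)
    rec <- synth_record(cfg, c("N", "S", "V", "N", "N", "S"), seed = 11,
                        morph_jitter = 0)
    fid <- synth_fiducials(rec, cfg)
    list(config = cfg, record = rec, fiducials = fid,
         beats = beat_windows(rec, fid))
  })
}

# a noisy multi-patient corpus for pipeline-level tests
small_corpus <- function() {
  fixture("small_corpus", function()
    synth_corpus(n_patients = 4, beats_per_patient = 30, seed = 99))
}

# independent brute-force oracle for the five degree descriptors
naive_descriptors <- function(adj) {
  n <- nrow(adj)
  deg <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && adj[i, j]) deg[i] <- deg[i] + 1L
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (adj[i, j]) edges[[length(edges) + 1L]] <- c(i, j)
  if (!length(edges)) return(rep(0, 5))
  keys <- vapply(edges, function(e)
    paste(sort(c(deg[e[1]], deg[e[2]])), collapse = "-"), character(1))
  tab <- table(keys)
  J <- as.numeric(tab) / length(edges)
  halfs <- vapply(names(tab), function(k)
    mean(as.numeric(strsplit(k, "-")[[1]])), numeric(1))
  c(sum(deg) / n^2, max(deg) / n,
    -sum(J * log2(J)), sum(J^2), sum(J * halfs) / n)
}

# independent brute-force pairwise-distance matrix
naive_weight_matrix <- function(pts) {
  n <- nrow(pts)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    w[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  mx <- max(w)
  if (mx > 0) w / mx else w
}

# cheap checksum of a standardizer's parameter set
digest_params <- function(sc) {
  sum(as.double(serialize(lapply(sc, signif, digits = 15), NULL)))
}

# planted-feature toy for wrapper selection: 5 informative of 20
make_planted_toy <- function(seed, n_per_class = 60) {
  set.seed(seed)
  gen <- function() {
    y <- rep(c("N", "S", "V"), each = n_per_class)
    shift <- c(N = 0, S = 1.2, V = -1.2)
    mu <- matrix(0, length(y), 20)
    for (j in 1:5) mu[, j] <- shift[y] * (1 + 0.1 * j)
    list(x = mu + matrix(stats::rnorm(length(y) * 20), length(y)), y = y)
  }
  list(train = gen(), valid = gen())
}
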