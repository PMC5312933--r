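# Cached study-scale fixtures shared by the acceptance tests: the default
# 2 Mb world (with sequence) plus its standard samples, built once.

default_world <- function() {
  if (is.null(.fixtures$default_world)) {
    .fixtures$default_world <- build_world(simulation_spec())
  }
  .fixtures$default_world
}

default_sample <- function(sample, sample_id = sample, overrides = list()) {
  key <- paste0("smp_", sample_id)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_tags(default_world(), sample,
                                      sample_id = sample_id,
                                      overrides = overrides)
  }
  .fixtures[[key]]
}

default_replicate_peaks <- function() {
  if (is.null(.fixtures$rep_peaks)) {
    w <- default_world()
    input <- default_sample("input")
    .fixtures$rep_peaks <- lapply(1:3, function(i)
      call_fixed_width_peaks(
        default_sample("ip", paste0("ip_rep", i)), input, w$genome))
  }
  .fixtures$rep_peaks
}

default_consensus <- function() {
  if (is.null(.fixtures$consensus)) {
    .fixtures$consensus <- consensus_peaks(default_replicate_peaks(),
                                           min_support = 2,
                                           peak_width = 200)
  }
  .fixtures$consensus
}

# match called peaks to the nearest planted site on the same chromosome;
# returns site index per peak (NA when none within max_dist)
match_peaks_to_sites <- function(peaks, sites, max_dist = 200) {
  ctr_t <- (start(sites) + end(sites) - 1) / 2
  ctr_p <- (start(peaks) + end(peaks) - 1) / 2
  schr <- as.character(seqnames(sites))
  pchr <- as.character(seqnames(peaks))
  vapply(seq_along(peaks), function(j) {
    i <- which(schr == pchr[j])
    if (!length(i)) return(NA_integer_)
    k <- i[which.min(abs(ctr_t[i] - ctr_p[j]))]
    if (abs(ctr_t[k] - ctr_p[j]) > max_dist) NA_integer_ else k
  }, integer(1))
}

# per-site center error of the best matching peak (Inf when unrecovered)
site_center_errors <- function(peaks, sites) {
  ctr_t <- (start(sites) + end(sites) - 1) / 2
  ctr_p <- (start(peaks) + end(peaks) - 1) / 2
  schr <- as.character(seqnames(sites))
  pchr <- as.character(seqnames(peaks))
  vapply(seq_along(sites), function(i) {
    j <- which(pchr == schr[i])
    if (!length(j)) return(Inf)
    min(abs(ctr_p[j] - ctr_t[i]))
  }, numeric(1))
}
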