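# Shared fixtures. The large parameter-recovery bundle is generated once
# per test run and cached; smaller fixtures are cheap enough to rebuild.

.fixture_cache <- new.env(parent = emptyenv())

# small default-world bundle for pipeline/synthetic tests
small_bundle <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_dataset(
      synthetic_config(n_promoters = 600, seed = 42))
  }
  .fixture_cache$small
}

# the acceptance-scale world: n = 20,000 promoters, fixed seed
big_run <- function() {
  if (is.null(.fixture_cache$big)) {
    cfg <- synthetic_config(n_promoters = 20000, seed = 101)
    gen <- generate_dataset(cfg)
    res <- analyze_bundle(gen$bundle)
    .fixture_cache$big <- list(cfg = cfg, gen = gen, res = res)
  }
  .fixture_cache$big
}

# a hand-sized catalog: 4 promoters on chr1/chr2, known coordinates
toy_catalog_bed <- function(dir = withr::local_tempdir(
                              .local_envir = parent.frame())) {
  bed <- c(
    "chr1\t10000\t10001\tpA\t0\t+",
    "chr1\t50000\t50001\tpB\t0\t-",
    "chr2\t10000\t10001\tpC\t0\t+",
    "chr2\t90000\t90001\tpD\t0\t-")
  path <- file.path(dir, "toy.bed")
  writeLines(bed, path)
  path
}
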