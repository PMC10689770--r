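# Shared small synthetic worlds, built once per test run.

tiny_cfg <- function(seed = 42, scale = 0.02, n_countries = 30, ...) {
  sim_config(scale = scale, n_countries = n_countries, seed = seed, ...)
}

build_fixture <- function(cfg) {
  world <- simulate_world(cfg)
  species <- simulate_species(world, cfg)
  keys <- simulate_keys(species, cfg)
  raw <- simulate_trade(species, world, keys, cfg)
  clean <- suppressMessages(harmonize_trade(raw, keys, species))
  classified <- classify_records(clean, species)
  list(cfg = cfg, world = world, species = species, keys = keys,
       raw = raw, clean = clean, classified = classified)
}

# one cached tiny world reused by read-only tests
tiny <- build_fixture(tiny_cfg())

# brute-force oracle for extract_name: test every key for substring
# occurrence, keep maximal length, break ties lexicographically last
oracle_extract <- function(text, keys) {
  low <- tolower(text)
  keys <- tolower(keys)
  vapply(low, function(tx) {
    hit <- keys[vapply(keys, function(k) grepl(k, tx, fixed = TRUE), TRUE)]
    if (length(hit) == 0) return(NA_character_)
    hit <- hit[nchar(hit) == max(nchar(hit))]
    sort(hit)[length(hit)]
  }, "", USE.NAMES = FALSE)
}

# dense multivariate-normal ML log-likelihood for the random-intercept
# model at a fixed variance ratio lambda (independent of the fitter's
# blockwise algebra)
oracle_lmm_loglik <- function(lambda, y, des, g) {
  g <- factor(g)
  Z <- stats::model.matrix(~ g - 1)
  n <- length(y)
  V0 <- diag(n) + lambda * tcrossprod(Z)
  V0i <- solve(V0)
  beta <- solve(t(des) %*% V0i %*% des, t(des) %*% V0i %*% y)
  r <- y - des %*% beta
  s2 <- as.numeric(t(r) %*% V0i %*% r) / n
  -0.5 * (n * log(2 * pi * s2) + as.numeric(determinant(V0)$modulus) + n)
}

# exhaustive nested-loop oracle for flow triples
oracle_flow <- function(classified, species, region_map, regions,
                        keep = NULL) {
  reg <- setNames(region_map$region, region_map$country)
  sp <- native_range(species)
  m <- matrix(0L, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (i in seq_len(nrow(sp))) {
    nm <- sp$accepted_name[i]
    if (!is.null(keep) && !(nm %in% keep)) next
    don <- unique(stats::na.omit(reg[sp$native_countries[[i]]]))
    ali <- classified[classified$accepted_name == nm &
                        classified$label == "alien", ]
    rec <- unique(stats::na.omit(reg[ali$country]))
    for (d in don) for (r in rec) m[d, r] <- m[d, r] + 1L
  }
  m
}
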