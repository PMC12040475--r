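# Small constructors used across test files.

make_obs <- function(values, times = seq_along(values) - 1, kind = "width",
                     id = "w1", species = "baboon", setting = "experimental",
                     replicate = 1L, unit = NULL) {
  out <- tibble::tibble(
    individual_id = id, species = species, setting = setting,
    time_days = times, kind = kind, value = values, replicate = replicate
  )
  if (!is.null(unit)) out$unit <- unit
  out
}

# Noiseless records: every individual heals exactly at `rate`.
make_linear_records <- function(rate = 0.6, n_id = 4, times = seq(0, 12, by = 3),
                                groups = "baboon") {
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(seq_len(n_id), function(i) {
      tibble::tibble(
        individual_id = sprintf("%s_%d", g, i), species = g,
        setting = "experimental", time_days = times,
        healing_distance_mm = rate * times, replicate = 1L
      )
    })
  })
}

study_relation <- function() ellipse_relation(0.121, 3.963)
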