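#' Read / write transplant pair experiments
#'
#' Two plain-text files carry a set of [pair_experiment()] objects: a YAML
#' design file (per pair: `local_pop`, `foreign_pop`, `distance_km`,
#' `local_N`, `foreign_N`) and a pot-level fitness CSV with a `pair_id`
#' column plus the pot columns.
#'
#' @param fitness_csv pot-level CSV path.
#' @param design_yaml design YAML path.
#' @return a list of `pair_experiment` objects.
#' @export
read_pair_experiments <- function(fitness_csv, design_yaml) {
  design <- yaml::read_yaml(design_yaml)
  pots <- utils::read.csv(fitness_csv, stringsAsFactors = FALSE)
  if (!"pair_id" %in% names(pots))
    stop_adaptdiff("fitness CSV needs a pair_id column")
  pots$germinated <- as.logical(pots$germinated)
  pots$survived <- as.logical(pots$survived)
  lapply(names(design), function(pid) {
    d <- design[[pid]]
    sub <- pots[pots$pair_id == pid, setdiff(names(pots), "pair_id")]
    if (!nrow(sub)) stop_adaptdiff("no pots for pair ", pid)
    pair_experiment(pid, d$local_pop, d$foreign_pop, d$distance_km,
                    d$local_N, d$foreign_N, sub)
  })
}

#' @rdname read_pair_experiments
#' @param pairs list of `pair_experiment` objects.
#' @export
write_pair_experiments <- function(pairs, fitness_csv, design_yaml) {
  design <- lapply(pairs, function(p)
    list(local_pop = p$local_pop, foreign_pop = p$foreign_pop,
         distance_km = p$distance_km, local_N = p$local_N,
         foreign_N = p$foreign_N))
  names(design) <- vapply(pairs, `[[`, "", "pair_id")
  yaml::write_yaml(design, design_yaml)
  pots <- do.call(rbind, lapply(pairs, function(p)
    cbind(pair_id = p$pair_id, p$pots)))
  utils::write.csv(pots, fitness_csv, row.names = FALSE, quote = FALSE)
  invisible(list(fitness_csv, design_yaml))
}
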