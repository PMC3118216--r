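# Curated promoter id-lists shipped with the package: the two narrowed
# initial promoter pools used besides the full-genome pool -- sigma-54
# dependent promoters, and the 57 promoters annotated as targets of response
# regulators of two-component systems (TCS).

#' Shipped initial-promoter-pool id lists
#'
#' @param which `"tcs_targets"` (57 ids) or `"sigma54"` (36 ids).
#' @return character vector of gene/promoter ids.
#' @export
promoter_id_list <- function(which = c("tcs_targets", "sigma54")) {
  which <- match.arg(which)
  fn <- switch(which,
               tcs_targets = "tcs_target_promoters.txt",
               sigma54 = "sigma54_promoters.txt")
  readLines(system.file("extdata", fn, package = "seedmotif",
                        mustWork = TRUE))
}
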