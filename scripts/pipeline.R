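#!/usr/bin/env Rscript
## Thin command-line front end over somatomap::runPipeline(): runs the full
## simulate -> connectivity -> lags -> GLM -> somatotopy pipeline and writes
## the report tables as TSV.
##
## Usage: Rscript scripts/pipeline.R [--seed <int>] [--subjects <int>]
##                                   [--outdir <dir>] [--decouple-con]

suppressMessages({
  library(optparse)
  library(somatomap)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--subjects", type = "integer", default = 20L),
  make_option("--outdir", type = "character", default = "pipeline_out"),
  make_option("--decouple-con", action = "store_true", default = FALSE,
              dest = "decoupleCon",
              help = "negative control: CON not coupled to inter-effector")
)))

status <- tryCatch({
  cfg <- defaultPipelineConfig(seed = opts$seed,
                               nSubjects = opts$subjects,
                               conCoupled = !opts$decoupleCon)
  rep <- runPipeline(cfg)
  dir.create(opts$outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(rep@tables)) {
    tab <- rep@tables[[nm]]
    if (is.matrix(tab)) tab <- data.frame(id = rownames(tab) %||% seq_len(nrow(tab)), tab)
    if (is.data.frame(tab))
      writeResultTable(tab, file.path(opts$outdir, paste0(nm, ".tsv")))
  }
  wta <- rep@maps$wta
  writeResultTable(data.frame(winner = wtaWinner(wta),
                              selectivity = wtaSelectivity(wta)),
                   file.path(opts$outdir, "wta.tsv"))
  message("stages: ", paste(rep@stages$status, collapse = " "))
  message("recovery checks: ",
          paste(names(rep@recovery), unlist(rep@recovery), collapse = "; "))
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("config", conditionMessage(e))) 2L else 1L
})
quit(status = status)
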