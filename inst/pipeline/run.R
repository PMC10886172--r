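#!/usr/bin/env Rscript
# Thin command-line driver over the aaamech pipeline:
#   Rscript run.R [--config cfg.yaml] [--wall-model hgo|mooney_rivlin]
#                 [--pressure 120|200] [--contact merged|penalty]
#                 [--level coarse|fine|finer] [--seed INT] [--outdir PATH]
#                 [--verify]
suppressPackageStartupMessages(library(aaamech))
suppressPackageStartupMessages(library(optparse))

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--wall-model", type = "character", default = NULL,
              dest = "wall_model"),
  make_option("--pressure", type = "double", default = NULL),
  make_option("--contact", type = "character", default = NULL),
  make_option("--level", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--outdir", type = "character", default = NULL),
  make_option("--verify", action = "store_true", default = FALSE)
))
opt <- parse_args(parser)

if (isTRUE(opt$verify)) {
  report <- verify_oracles()
  print(as.data.frame(report))
  quit(status = if (all(report$pass)) 0 else 1)
}

cfg <- pipeline_config(file = opt$config)
if (!is.null(opt$wall_model)) cfg$wall_model <- opt$wall_model
if (!is.null(opt$pressure)) cfg$pressure$target <- opt$pressure
if (!is.null(opt$contact)) cfg$contact <- opt$contact
if (!is.null(opt$level)) cfg$level <- opt$level
if (!is.null(opt$seed)) cfg$seed <- opt$seed
if (!is.null(opt$outdir)) cfg$outdir <- opt$outdir

res <- run_pipeline(cfg)
cat(sprintf("artifacts written to %s\n", res$outdir))
print(as.data.frame(res$summary))
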