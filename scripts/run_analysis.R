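#!/usr/bin/env Rscript
# Thin command-line wrapper over run_full_analysis():
#   Rscript scripts/run_analysis.R --in panel.csv --out report.json
#     [--start-weekday Mon] [--max-lag 63] [--lb-lags 21]

suppressPackageStartupMessages(library(memlag))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1L]
}
infile <- get_arg("--in")
outfile <- get_arg("--out", "report.json")
if (is.null(infile)) stop("usage: run_analysis.R --in panel.csv --out report.json")

panel <- read_panel_csv(infile, start_weekday = get_arg("--start-weekday"))
report <- run_full_analysis(panel,
                            max_lag = as.integer(get_arg("--max-lag", "63")),
                            lb_lags = as.integer(get_arg("--lb-lags", "21")))
print(report)
write_report_json(report, outfile)
cat("report written to", outfile, "\n")
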