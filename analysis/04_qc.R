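#!/usr/bin/env Rscript
# Run the seven-step quality-control cascade over every cohort sample and
# assemble the read/base-pair accounting report.
source("analysis/00_config.R")

cdir <- file.path(DATA, "cohort")
meta <- fread(file.path(cdir, "metadata.tsv"))
cfg <- filter_config()

tallies <- rbindlist(lapply(meta$sample, function(s) {
  qc <- qc_pipeline(file.path(cdir, paste0(s, "_1.fastq.gz")),
                    file.path(cdir, paste0(s, "_2.fastq.gz")), cfg)
  out <- file.path(DATA, "clean")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_fastq(qc$pairs$r1, file.path(out, paste0(s, "_1.fastq.gz")), 1)
  write_fastq(qc$pairs$r2, file.path(out, paste0(s, "_2.fastq.gz")), 2)
  cbind(data.table(sample = s), qc$tally)
}))
rep <- qc_report_summary(tallies, read_length = 150)
fwrite(tallies, file.path(OUT, "qc_tallies.tsv"), sep = "\t")
jsonlite::write_json(rep[c("totals", "averages", "n_samples",
                           "conservation", "nominal")],
                     file.path(OUT, "qc_report.json"), auto_unbox = TRUE,
                     digits = NA)
message(sprintf(
  "input %s reads (%s on average) -> surviving %s (%s on average); %s bp",
  format(rep$totals$input_reads, big.mark = ","),
  format(rep$averages$input_reads, big.mark = ","),
  format(rep$totals$surviving_reads, big.mark = ","),
  format(rep$averages$surviving_reads, big.mark = ","),
  format(rep$totals$surviving_bp, big.mark = ",")))
message("conservation (input = surviving + discarded) holds: ",
        rep$conservation)
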