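#!/usr/bin/env Rscript
# Screen the simulated panel for the four TE families, call three-state
# presence per species, and compare against the simulation truth.
# Reads results/sim/, writes results/screen/.

suppressMessages(library(httrace))

indir <- "results/sim"; outdir <- "results/screen"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
manifest_open(file.path(outdir, "run_manifest.txt"))

fams <- read_fasta(file.path(indir, "te_library.fasta"))
species <- sub("\\.fasta$", "",
               grep("^[A-Z]", list.files(indir, "\\.fasta$"), value = TRUE))
species <- setdiff(species, "te_library")
genomes <- lapply(species, function(sp)
  read_fasta(file.path(indir, paste0(sp, ".fasta"))))
names(genomes) <- species

scr <- screen_panel(as.character(fams) |> setNames(names(fams)), genomes,
                    search_params("relaxed"), verify = fams)
write_presence_matrix(scr$calls, file.path(outdir, "presence_calls.tsv"))

truth <- read_presence_matrix(file.path(indir, "truth_presence.tsv"))
called <- scr$calls[rownames(truth), colnames(truth)] == "present_similar"
agree <- mean(called == (truth == "present"))
ht_log("02_screen: ", nrow(scr$calls), " families x ", ncol(scr$calls),
       " species; agreement with simulation truth = ", round(agree, 4))
stopifnot(agree == 1)
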