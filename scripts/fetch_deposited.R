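#!/usr/bin/env Rscript
# Fetches the 14 deposited opsin gene records (GenBank KM276762-KM276775)
# as translated CDS proteins and stores them under inst/extdata/deposited/.
# Requires network access to NCBI E-utilities; run once from the package
# root.  The offline test suite treats the file as optional input.

accs <- sprintf("KM%06d", 276762:276775)
dir.create("inst/extdata/deposited", recursive = TRUE, showWarnings = FALSE)
out <- "inst/extdata/deposited/af_opsins_aa.fasta"
url <- paste0(
  "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
  "db=nuccore&id=", paste(accs, collapse = ","),
  "&rettype=fasta_cds_aa&retmode=text")
message("fetching ", length(accs), " records from NCBI ...")
ok <- tryCatch({
  utils::download.file(url, out, quiet = TRUE)
  TRUE
}, error = function(e) FALSE, warning = function(w) FALSE)
if (!ok || !file.size(out) > 0) {
  if (file.exists(out)) unlink(out)
  stop("download failed; network access to eutils.ncbi.nlm.nih.gov is required")
}
message("wrote ", out)
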