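# Writes a minimal centroided mzML file (64-bit little-endian, uncompressed)
# for exercising the mzML reader without binary fixtures in the repository.

write_tiny_mzml <- function(path, scans) {
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  spectrum <- function(idx, rt, pol, mz, inten) {
    polcv <- if (pol == "pos") {
      "MS:1000130\" name=\"positive scan"
    } else {
      "MS:1000129\" name=\"negative scan"
    }
    sprintf(paste0(
      "<spectrum index=\"%d\" id=\"scan=%d\" defaultArrayLength=\"%d\">",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000511\" name=\"ms level\" value=\"1\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\"/>",
      "<cvParam cvRef=\"MS\" accession=\"%s\"/>",
      "<scanList count=\"1\"><cvParam cvRef=\"MS\" accession=\"MS:1000795\" name=\"no combination\"/><scan>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000016\" name=\"scan start time\" value=\"%f\" unitCvRef=\"UO\" unitAccession=\"UO:0000031\" unitName=\"minute\"/>",
      "</scan></scanList><binaryDataArrayList count=\"2\">",
      "<binaryDataArray encodedLength=\"%d\"><cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\"/><cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\"/><cvParam cvRef=\"MS\" accession=\"MS:1000514\" name=\"m/z array\" unitCvRef=\"MS\" unitAccession=\"MS:1000040\" unitName=\"m/z\"/><binary>%s</binary></binaryDataArray>",
      "<binaryDataArray encodedLength=\"%d\"><cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\"/><cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\"/><cvParam cvRef=\"MS\" accession=\"MS:1000515\" name=\"intensity array\" unitCvRef=\"MS\" unitAccession=\"MS:1000131\" unitName=\"number of detector counts\"/><binary>%s</binary></binaryDataArray>",
      "</binaryDataArrayList></spectrum>"),
      idx, idx + 1L, length(mz), polcv, rt, nchar(enc(mz)), enc(mz),
      nchar(enc(inten)), enc(inten))
  }
  body <- paste(vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    spectrum(i - 1L, s$rt, s$polarity, s$mz, s$intensity)
  }, character(1)), collapse = "")
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">",
    "<cvList count=\"2\"><cv id=\"MS\" fullName=\"MS\" URI=\"x\"/><cv id=\"UO\" fullName=\"UO\" URI=\"y\"/></cvList>",
    "<fileDescription><fileContent><cvParam cvRef=\"MS\" accession=\"MS:1000579\" name=\"MS1 spectrum\"/></fileContent></fileDescription>",
    "<softwareList count=\"1\"><software id=\"s\" version=\"1\"/></softwareList>",
    "<instrumentConfigurationList count=\"1\"><instrumentConfiguration id=\"i\"/></instrumentConfigurationList>",
    "<dataProcessingList count=\"1\"><dataProcessing id=\"dp\"><processingMethod order=\"1\" softwareRef=\"s\"><cvParam cvRef=\"MS\" accession=\"MS:1000544\" name=\"Conversion to mzML\"/></processingMethod></dataProcessing></dataProcessingList>",
    "<run id=\"r\" defaultInstrumentConfigurationRef=\"i\">",
    sprintf("<spectrumList count=\"%d\" defaultDataProcessingRef=\"dp\">%s</spectrumList>",
            length(scans), body),
    "</run></mzML>")
  writeLines(doc, path)
  invisible(path)
}
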