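#' Total genetic length of a map
#'
#' Sum over chromosomes of (last cM position - first cM position). With the
#' default synthetic 22-autosome preset this equals 3662.5 cM, the maximum
#' attainable ICS value (reached when every locus shares at least one
#' allele).
#'
#' @param map a [GeneticMap-class].
#' @return total genetic length in cM.
#' @examples
#' m <- makeSyntheticMap(seed = 1)
#' totalMapLength(m)
#' @export
setGeneric("totalMapLength", function(map) standardGeneric("totalMapLength"))

#' Number of loci
#' @param x a map-bearing object.
#' @return integer locus count.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Per-chromosome genetic lengths
#' @param map a [GeneticMap-class].
#' @return named numeric, cM span per chromosome.
#' @export
setGeneric("chromosomeLengths",
           function(map) standardGeneric("chromosomeLengths"))

#' Sample identifiers
#' @param x an object holding samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Genotype dosage matrix (loci x samples; 0/1/2 allele-1 count, NA missing)
#' @param x a [DiploidGenotypes-class] or [KinCohort-class].
#' @return integer matrix.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' The genetic map carried by an object
#' @param x an object with an associated map.
#' @return a [GeneticMap-class].
#' @export
setGeneric("geneticMap", function(x) standardGeneric("geneticMap"))
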