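# hg19 autosomes: lengths and UCSC gap-track centromere coordinates (0-based half-open)
name	length	cen_start	cen_end	acrocentric
chr1	249250621	121535434	124535434	FALSE
chr2	243199373	92326171	95326171	FALSE
chr3	198022430	90504854	93504854	FALSE
chr4	191154276	49660117	52660117	FALSE
chr5	180915260	46405641	49405641	FALSE
chr6	171115067	58830166	61830166	FALSE
chr7	159138663	58054331	61054331	FALSE
chr8	146364022	43838887	46838887	FALSE
chr9	141213431	47367679	50367679	FALSE
chr10	135534747	39254935	42254935	FALSE
chr11	135006516	51644205	54644205	FALSE
chr12	133851895	34856694	37856694	FALSE
chr13	115169878	16000000	19000000	TRUE
chr14	107349540	16000000	19000000	TRUE
chr15	102531392	17000000	20000000	TRUE
chr16	90354753	35335801	38335801	FALSE
chr17	81195210	22263006	25263006	FALSE
chr18	78077248	15460898	18460898	FALSE
chr19	59128983	24681782	27681782	FALSE
chr20	63025520	26369569	29369569	FALSE
chr21	48129895	11288129	14288129	TRUE
chr22	51304566	13000000	16000000	TRUE
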