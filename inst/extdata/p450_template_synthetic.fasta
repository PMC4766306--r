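>P450_template_synthetic synthetic cytochrome P450 template
KWIPMFPLDMCTTINIVINVRAPRNCKCYQTFDMCMMKGPSSWVIPYNEKMSVLINWGTT
WHARHIPFHKTREHDFIRHKTIHCYFDVTTKSVHQYRLWGHESRFDICEMTGFCAFDCKN
RQHKHCGTDQHAILHHAASPREQFNFMPMDMNNLEYRVMCIYQIIFSSDPMCFPFQWKML
PPYKMYTYTDSFDTFHSKALCHYWGASVCEWTHCEVTMGSGHVSQETCQDWRPDLMTFEM
FGWGQQTTEIGRQGMHKPSDKTQTIMSWVIINCEVFCHAEHFTELMFLNYKKWKHMTKNC
CQLHRHDFPQVGDLRNMSSIAGFDTTRMSKQEWKSHCILSICDQCPQNCTYEMHESGSGW
KEQMPIYKQKHVKREILIMPEYCDKLEALRGNQVIYRGYSHPMPWWTVRNGVYMMHTQTQ
KSLHWKALQPERFDQYMELVSQIHEKPKEGQAMCGSFKMRSGSFGAGRRVCLGQKHCDYF
FVGEVTECPAAQVPMNKYQT
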