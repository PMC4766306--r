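>refP450_01 synthetic reference P450 (90% id to template)
KGIPMFYLDMCTTINIVINFRAPINCKCYQTFDMCMMKGPSSWVGPYNEKMSVLINCHTT
WHANHIPFHSIRKHDFIRHCTIHCYFDVTTKSVHQYRLWGHESRFDICEMTGFCAFDCKN
RQHKHCFTDQHATLHHAASPREQCNFMPMDMNNLEYRVMCIYQIIFSSDPMCFPFQWKML
PPYKMLTYTDNFDTFHSKALCHYWGFSVCEWTHCEVTMGSGHVSQETCEDWRPDLWWFEM
FGWGQGTTEIGEQGMHKPSDKTQTIMSWVIINCEVFCHAETFTELCILNYDKWMHMPKNS
CQLHRHDVPQVGDHRNMSSIAGFDTTRMSKQEIKSHCILSICDQCPQNCTYWMHEWGSGW
KEQMPIYKQKIVIREILIMPEYCDKLEALRGNQVIYRFYSHPMPWWTVRNGWYMMVTQTQ
KSPRWKLDQPERFDQYMELVSQIHEKPKEGQAMCGSFKTRSTSDGAGRRVCRGDKHCDYF
FVGHVTECPAAQVPMNKYQT
>refP450_02 synthetic reference P450 (87% id to template)
KWIPMFALYMCTKINIVICIRAPRICKCYQVFDMCMMKGQSSWVWPYNEKMAVGIWWGTT
WHARHIPIHKTRTHGFIRHKTIHCYFDVMPKSVCQYMLMGHESRFWICEMTGFCAFDCKN
RQHKHCGTDQHAILHHAASPREHFNFMFMDMNNLEYRVMCIYQIIFSSDDMCFPFQWKML
WPYFMYTYTDSFDDFHMKASCHYWGASVCEWLCCEVTMGSGHVSQETCQDWRPQLMTPEM
FGWTQQTAEIGRQGMHKPSDKHQTIMSWVIINDEAFCHAEHGAELPFLNYKKWKHMTKNC
CQDHRSDFNQVGDLRNMSSIAGLQYTRMSTQEWKSHCILSICDQCPQNCTYEMHESGSGW
KEQMPIYKQKVVKLEILIMPEMCDKLEALRGNQVIYRGYSHPMTWWTVRNQVYMMHTQTQ
KSLHWKAESPERFDQYCELVSQIHEKPKEGQCMCGSRKMRLGSFGAGRRVCLGQKTCDYI
FVGWVTEAPAAQVPMNYYQN
>refP450_03 synthetic reference P450 (84% id to template)
KWIPWFPLDSCTTINIVLNDNWPRNCKCYQTFDMCSMKGPSAWLIPYNEQMSVLANWGTT
WHARHIRFHKTRLGDFIDHHDIHCYFQVTTLSQHQYRPWGHESRFDICEMTGYMAFDCKN
RQHKHCNTDQHAILHHKACPREQFNFMPMDMNNLFYRRMCIYTIIFSSDPMCFPRQWKML
GPYKMYTTTDSFRTFHSKAKCHYWGASVVEWTHRCVSMGSGFVSQETCQDWRPPLMTFEM
FGWGAQTTEIGRQDMHKPSLKTQTIMSWVNINCRVFCHAMGFTELMFGNYKKWKHMTKNC
CWLSRHDFPQVGDLRNMSSIAGFDTTRRSKQEEKSHCNLSICDQCPQNCTREMHESGSSW
TEQMPIYHQKHVKREILIMPSYCDKLEALRGIQVITRGYSHPMPWGTVRNGVYMFHWQHQ
KSLHWKALQRERFDQYMCLVSVIHEKPKNGGYMCGEFSMRSYSFGAGRRIDLGQKHCDYF
PVGEVLEMPAAQVAMNKYNT
>refP450_04 synthetic reference P450 (81% id to template)
KWYPMSPLCYCTTIYIVINVRAPRNCKCYQTFDMCMMKGISSWVIPYSEKMGVLRNWMTT
EHFRHIPFHKPRFHYFIHHKTTHCYFLVTTKSQHQYRLWEHESSSDIPEMTGFDAFDPKN
RQHKHCGEDQHAWLHHAAYPREQFIFMPMDQNLLEIRVMCIYQIYFSKDPMCFKFQWKCL
PPYTMYTQTDSFDLVHRKNLCHYQHASVCEWTHCEVTMGILDVSNETCQDANPDSMTFEM
FGAGDQTTEIGRQGMHIPSDKTQTIMEWVPIQCEVFCHAEHFTELMKLVYKKWKHMFKQC
HQLHRHFFPQVGDLRNMSSIAGWDTTRMSKLEWKSHCILSHCMQCWRNCTYEMHESGSKW
KYQMPIQLMKHVKPEIGQMPEYCDKLNALRGNQVIYRGYDHPMPPWTVRNGVYMMHTQTQ
KYLHIAALQPEHFDQYMYLVSTIHEKPAEDQAFCGSFKMRSGSFGAGRNVCLGQGHCDYF
FVGEFTEGPAATIPMNKYQT
>refP450_05 synthetic reference P450 (78% id to template)
KWIPMDPLKMDTTINIVHNVRAPGNCTCYQTCDMCKFKGPSNWVIPYNEKMSVLIPWKTT
WAARHIRSQKTREHDFRNHKMIECVASHTTYSMHQARLWGHESFFDICIMTGHCAFDCKN
RQHKHCGTDQFAILHHAASPREQFNFMPMDCGNLEYRVMCIYQSIFSSDRTCTPFQWKML
SPYKMYTYDWSVHWFHPKALCHHWGISVWEWTHCECTMGHGHVSQETCQDKRMDLMTVEN
PGSKQQTCEDGRIGMAKPSDKTQTNMSWVIENCEVFCMIELFTELMFVFGKKWKHMTKNC
CQLHMHDFEQVGDLDNMSSITGFRPTGMSGQEWLSHCILSIDDQCPQNCTYYMLESGSPW
KEQMPIYKQQHVKRELKIMPKCCHKLEKLRGNQVIYRGYSHPMPWWTQHNGVHMMITQTQ
HSLHLMALQPERFDQYMEPRSQIHENPQEGQAMCLEHKMRVTSDGAGRRVCLGQMHCDYF
FVGEVTECPTAQVEWNKYQQ
>refP450_06 synthetic reference P450 (75% id to template)
KWIPVFPLDYYWTSNIVIGFRALENKKIYQTSGMCMMKSPGMWVYMTNEKMSVLFNWRLT
WHARHIPFHKTREHDFIIIKVIICYFDVTRKSIEQYRLWGHELRFDICEWPGFCAFVEDN
YQHKHKLTDQHKILHNSASPNEQFNFMPMDMNNFEYRVMCSYQIIFSSDPHCFPDQWKSL
PPYQSITYTISFDTFHSKMLCHYWGASVLEWTHVEMTMDSGHRSQETCVDWRPDLMTFLM
FIWGQQCYEIGRQGMHKYSCNTATIMLWSIILCEVFCHAEHFGELMFLNYKKIPHMTAND
CQLQRHDFPHVQDLRHMHSICFFNPWRMSKQQWKSHKILSICDCCPQVCTYGMHESWSKC
KEQMPIMKHLHCTREILIQPEYCDKLEVLVCWQKIPRGYSMPMPTWTHRQGSYMMHMQTQ
KSALWKALQAEFFDQYMQLVSQIDEKPKEGQWMCGSDKQRSGSFGAGRRVCLGQKHCMYF
CVGEVTECPAAQMVKNDYQT
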