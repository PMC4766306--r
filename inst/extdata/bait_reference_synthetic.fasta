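>bait_reference_synthetic synthetic bait methyltransferase
IEPTVVVCVTLLHSQFPRCIHGPLVHDPTPKAMNPILYRVYLMGAMFYFTANMWVCFGIW
ITDVHRAYCSKLTNFDHVNLCVCPIHRVQIMPVGCLVCMNQGCRCGQFAKPLKACRVKDR
WWHNWFAQFMCCSLMVSEDKPMLCEELSMRSEWFPCHQQCAPWGTAKQSCFHPHHDIFDY
VIPMMLCDNTQPVWWMFLEFRGLFAIVFAEVKAMRKSIRPRPNLSITAFQWCAPVLPQYL
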