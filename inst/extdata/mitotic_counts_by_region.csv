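class,region,g1,mitotic
MAGE-A,membrane,4639,4337
MAGE-A,luminal,1187,1617
SOX9,membrane,6993,941
SOX9,luminal,1984,206
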