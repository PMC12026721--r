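athlete_id,locus,fragments_bp
S001,ACE,596.5;316
S001,PPARA,265.2;214.1;48.1
S001,CKM,356.3;201.2;152
S002,ACE,601.6;319.6
S002,PPARA,265.3;214.7;48.2
S002,CKM,206;155
S003,ACE,596.4
S003,PPARA,218.6;47.2
S003,CKM,209.7;154.2
S004,ACE,320.2
S004,PPARA,214.2;48.8
S004,CKM,359.2
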