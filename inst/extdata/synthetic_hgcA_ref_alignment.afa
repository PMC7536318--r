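>hgcA_ref01
KHQMNVVHHKHIFKHMEHIGYWSRDMWRTNNGHTCYIWGSVRNCMYWLMCECEQTHDGKINVWCAAGKTRCCPNEMDRWRMNQTYQCYVQIGICAQELLTQTYLWVWDDSDFMNFFAHKCVCYYYLPRWSDPHQRKFAYSSAFFRHGVPH
>hgcA_ref02
KHQMNVRHHKHIFQEMEHIGYWSRDMWRTNNGHTCYKWGSVRNCMYWLMCECEQFHDGKANVWCAAGKTRCCTNEMDRWRMNQTYQCYVYIGICAQELLTQTYLWVWDDSDFMNFFAHKVVFYYYLPRWSDSHQRKFAYSSAFFRHGIPH
>hgcA_ref03
KHQMNVRHHKHIFQEMEVIGYWSRDMWRTNNGHTCYKWGSVRNCMYWLMCECQQTHDGKANVWCAAGKTRCCTNEMDRWRMHQTEQCYVYIGITAQELLTQTYLWVWDDSDFMNFFAHKCVCYYYLPRWSDPHQRKFAYSSAFFRHGQPH
>hgcA_ref04
KHQMNVRHHKHIFQEMEHIGYWSRDMWRTNNGHTCYKWGSVRNCMYWLMCEHEQTHDGKANVWCAAGKTRCCTNEMFRWRMNQTYQCYVYIGICAMELLTQTYLWVWDDSDFMNFFAWKCVCYYYLPRWSDPHQRKFAYSSAFMRHGQPH
>hgcA_ref05
KHQMNVRHHKHIFQEMEGIGYFSRDMWRTNNGHTCYKWGSVRNCMYWLMCECEQTHDGKANVWCAAGKTRCCTNEMDRWRMNQTYQCYVYIGICAQELLTQTYLWVWDDSDFMNFFCHKCVCYYYLPRWSDPHQRKFAYSSAGERHGQPH
>hgcA_ref06
YPQMNVRHHKHIFQEMWHIGYWSRDMWRTNNGHTCYKWGSVRNCMYWLMCECEQTHDGKANVWCAAGKTRCCTNEMDRWRMNQTYQCYVYIGICAQELLTQTYLWVWDDSDFMNFFAHKCVCYYYLPRWSDPHQRKFAYSSAFFRHGQPH
>hgcA_ref07
KHQMNVMHHKHIFQEMEHIGYWSRDMWRTNNGRTCYKWGSVRNCMYWLMCECEQTHDGKYNVWCAAGKTRCCTNEMDRWRMNQTYQCYVYIGHCDQELLTQTYLWHWDDSDFMNFFAHKCVCYYYLPRWSDPHQRKFAYSSAFFRHGQPH
>hgcA_ref08
KHQMNVRHGKHIFQSMEHIGYWSRDMWRTNNGHTCYKWGSVANCMYWLMCECEQTHDGKANVWCAAGKTRCCTNEHDRWRMNQTYMCYVYIGFCTQELLTQTYLWVWDDSDFMNFFAHKCVCYYYLPRWKDPHQRKFAYSSAFFRHGQPH
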