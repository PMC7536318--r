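>SYNREF01
KHQMNVRHHKHICQEMEHIGAWSVDMWRTNNCHCCYKWGSVRTVMKWLMCECEQTHDGKANVWCAAGKTRCCTNEMFYFRMNQTYQCYVYIGIPAQELLTQTYEWHWHDIDFMAHFAFKCVGMYYLPRWHDPHQYKFAYSFHSFGPEQPH
>SYNREF02
KHQMSVRHHKHIFQEMEHIGAWSVDMWRTNNCHCCYKWGSGRTVMKWLMCECEQFHDGKANVWCAAGKTRCCTNEMFYFRMNQTYQCYVYIGKPAQELQTQTYEWHWHDIDFMAHFAFKCVGMYYLPRWHDPHQYKFAYSSASFGPEQPH
>SYNREF03
KHQMNVRHHKHIFQEMEHIGAWSVDMWRTNNCHCCYKWGSVRTVMKWLMCECEQTHDGKANVWCAAGKTRCCTNEMFYFRMNQTYQCYVYIGIPAQELLTQTYEWHWHDIDFMAHFAFKCVGMYYLPRWHDPHQYKHAYSSASFGPEQPH
>SYNREF04
KHQMNVRHCKHIFQEMEHIGAWSVDMKRINNCHCCYKWGSVRTVMKWLMCECEQTHDRKANVWCAAGKTRCCTNEMFYFRMNQTFQCYVYIGIPAQELLTQTYEWHWHDKDFMAHFAFKCVGMYYLPRWHDPHQYKFAYSSASFGPETPH
>SYNREF05
KHQQNVRHHKHIFQEMEHIGAWSRSMWRTNNGMCCYKWGSVRNVMYWNMCEHEQTHDGKANVWCAAGKTRNCTNNMPRFRMNQTYQCYVYIGIPTQELLTQTYEWHWHHHDFMAFFAFKMVGPHSLPRWSVPFQYKFAYSSAFFGHEKPH
>SYNREF06
KHQQNVRHHKHIFQEMEHIGAWSRSMWRTNNGMCCYKWGSVRNVMYWLMCECEQTHDGKANVWCAAGKTRNCTNNMPRFRMNQTYQCYVYIGIPTQELLTQTYEWHWHDIDFMAFFAFKMVGPHSLPRWSVPHQYKFAYSSAFFGHEKPH
>SYNREF07
KHQPNVRHHKHDFWEMEHIGAWSRSMWRTNNGMCCYKWGSVRNVMYWLMCECEQTHDGKANVWCAAGKTRNCTKNMPRFRMNQTYQCYVYIGIPTQELLTQTYEWHWHDIDFMAFFAFFMVGPHSLPRWSVPHQYKFAYSSAFFGHEKHH
>SYNREF08
KHQQNVRHHKHIFQEMEHIGAWSRSMWRTNNGMCCYKWGSVRNVMYWLMCECEQTHDGKANVWCAAGKTRNCTNNMPRFRMNQTYQCYVLIGIPTQELLTQTYEWGWHDIDFMAFFAFKMVGPHSLPRASVPHQYKFAYSSAFFGHEKPH
>SYNREF09
KHQMNVRHHRHIHCEMFHIGYWSRPIWRTNNGHTCSCQGSVPMRRYWLMCENEQTHDGKANVWCAAGKTRCCTNEMDRWRMLQTYQCWVYIGCCAWELLIQTYLWCFDYQVFDNFFAHKCVCYYYLDRWFDPHQRIFPTSVAFFRHSQPH
>SYNREF10
KHQMNVRHRKEIFCEMEHIGYWSRPMHRTNNGHTCSCQGSVPMRMYWLMCENEQTHDGKANVWCAAGKTRCCTNEMDRWRMLQTYQCWVYIGCCAWELLIQTYLWCFDYQVFDNFFAHKCVCYYYLDRWFDPHQRCFPFSVAFFRHSQPH
>SYNREF11
KHQMNVRHHKHIFCEMEHIGYWSRPMWRTNNGHTCSCQGSVPMRRYWLMCENEQCHDGKANVWCAAGKTRCCTNEMDRWRMLQTYQCWGYIGCCAWELLIQTYLWCFDYQVFDNFFAHKCVCYYYLDRWFDPHQRCFPTSVAFFRHSQPH
>SYNREF12
KHQMNVRHHKHIFCEMEHIGYWSRPMWRTNNGHTCSCQGSVQMRRYWLMCENEQTHDGKANVWCAAGKTRCCTNEMDRWRMLQTYQCWQYIGCCAWELLIQTYLWCFDYQVFDNFFAHGCVCYYYLDRWFDPHQRCFPTSVAFFRHSQPH
>SYNREF13
KHQMNVRHHKHIFQEMEHRWYWSRDMWRTNNGHTCYKWGSVKNCMYWLMVFTEVTHDGKTNVWCAAGKTYCCMNFMFRWRMNITIQCYAYLGHCAQPLLHTTYLWGTDDSDPMNFSAHKCVVYYYLPCWSDPHQQDFALSSAHFRHGIPH
>SYNREF14
KHQMNVRHHKHIFQEMEHRGYWSRDMWRTNNGHTCYKWGSVKNCMYWLMCHTEQTGDGKTNVWCAAGKTMCCWNFMFRWPMNQTNQCPAYLGHCAQPLLHTTYLWGTDDSQPMNFSAHKCVVYYHLPCWSDPHQQDFALSSAHFYHGQNH
>SYNREF15
KHQMNVRHHKHIFQEMWHRGYWSRDMWRTNEGHTCYKWGSVKNCMYWLMCFTEQTHDGKTNVWCAAGKTRCCWNFMFRWDMNQTNQCYAYLGHCAQPLLHTTYLWGTDDSDPMRFSAHKCVVAYYLPCWSDPHQQDFALSSAHFRHGQPH
>SYNREF16
KHQMNVRHHKHIFQEMEPRGYWSRDMWRTNNGHTCYKWGSVKNFMYWWMCFTEQTHDGKTNVWCAAGKTRCCWNFMFRWRMNQTNQCYAYLGHCAQRLLHTTYLWGTDDSDPMNFSAKRCVVYYYLPCWSDPHQQDFALSSVHFRHGQPH
>SYNREF17
KHLMNVRHNFHDFQGMEAIGYSSRDSQRTLNGHTCYKWGWVRNETYWLMCECEQTFDGKANVWCAAGKTRCCTNEMDDGRMNQWYMCYVYIGGCCQELLTQTYIWVWDDSDFMNFIAHKCVCYWYYPCLSDAMRRKFAYSSWFFRHGQPH
>SYNREF18
KHLPNVRHNFHDFQGMEAIGYSSRDSWRTLNVITCYKWGSVRNETYWLMCECENTFDGKANVWCAAGKTRCCTNEMDRGRMNQWYMCYVYIGGCCQELLTQTYYWVWDDSDLMNFIAHKCVCYYYYPCLSDAMRRKFAYSSWFFRHGQPH
>SYNREF19
KHLMNVRHNFHDFQGMEAIGYSSTDSWRTLNGHTCYKWGSVRNETYNLMCECEQTFDGKANVWCAAGKTRCCTNEPDRGRMNQWYMCYVYIGGCCQELLTQTYIWVWDDSDFMNFIAHKCVCYYYYPCLSDAMRRKFAYSSWFFRHGQPH
>SYNREF20
KHLMNVRHNFHDFQGMEAIGYSSRDSWRTLNGHTCEKWGSVRNETYWLMCECEQTFDGKANVWCAAGKTRCCTNEMDRGRMNQWYMCYVYGGGCFQELLTQTYIWVWDRSDFSNFIAHKCVCYYYYPCLSDAMRRKFAYSSWFFRHGQPH
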