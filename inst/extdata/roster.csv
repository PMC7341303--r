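id,abbrev,sex,age,age_category,group,origin
bonbon,bo,male,14,young,captive,Tama
deckie,de,male,41,adult,captive,Wild
gin,gi,male,11,young,captive,Tama
max,mx,male,12,young,captive,Tama
fubuki,fu,male,5,juvenile,captive,Tama
peach,pc,female,29,adult,captive,Izu
nana,na,female,36,adult,captive,Tama
peco,pe,female,58,adult,captive,Wild
chico,ci,female,25,adult,captive,Tama
cherry,ch,female,29,adult,captive,Tama
berry,be,female,19,adult,captive,Tama
momoko,mo,female,26,adult,captive,KS
mikan,mi,female,13,adult,captive,Tama
marina,mr,female,29,adult,captive,KS
mil,ml,female,16,adult,captive,Tama
sakura,sa,female,10,young,captive,Noichi
alofu,AL,male,20,adult,wild,M
bonobo,BB,male,21,adult,wild,M
carter,CT,male,17,adult,wild,M
kalunde,DE,male,39,adult,wild,M
fanana,FN,male,24,adult,wild,M
hanby,HB,male,22,adult,wild,M
masudi,MA,male,25,adult,wild,K
pimu,PM,male,14,young,wild,M
cynthia,CY,female,20,adult,wild,O
nkombo,NK,female,32,adult,wild,K
opal,OP,female,31,adult,wild,O
pinky,PI,female,30,adult,wild,O
totzy,TZ,female,20,adult,wild,M
wakusi,WX,female,41,adult,wild,O
christina,XT,female,27,adult,wild,O
zola,ZL,female,15,adult,wild,O
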